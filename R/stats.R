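# Statistical layer: distribution checks, group comparisons with compact
# letter displays, correlation with Fisher-z intervals, and PCA with the
# Kaiser retention rule.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness statistic and the Anscombe-Glynn
#' kurtosis statistic into `K2 = Z_skew^2 + Z_kurt^2`, referred to a
#' chi-squared distribution with 2 df. Requires `n >= 8`.
#'
#' @param x Numeric sample.
#' @return List with `k2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("the omnibus test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("sample is constant")
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # D'Agostino (1970) transformed skewness
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # Anscombe-Glynn (1983) transformed kurtosis
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Distribution checks and test-branch routing
#'
#' Normality is assessed with the D'Agostino-Pearson omnibus test on the
#' pooled within-group residuals (single groups of n = 5 are below the
#' test's validity, so residuals are pooled across groups); variance
#' homogeneity with the median-centred Levene (Brown-Forsythe) test. The
#' routing decision sends the variable to the parametric branch only when
#' both tests are available and non-significant at `alpha`.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor (same length).
#' @param alpha Routing significance level.
#' @return Object of class `distribution_check`: `normality_p`, `levene_p`,
#'   `branch` (`"parametric"` or `"nonparametric"`), and flags
#'   `insufficient_n`, `constant_data`.
#' @export
check_distribution <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  resid <- values - stats::ave(values, groups)
  insufficient <- length(resid) < 8
  constant <- stats::var(values) == 0
  normality_p <- NA_real_
  levene_p <- NA_real_
  if (!insufficient && !constant) {
    normality_p <- dagostino_pearson(resid)$p
  }
  if (!constant && nlevels(groups) >= 2) {
    lev <- car::leveneTest(values ~ groups, center = stats::median)
    levene_p <- lev[["Pr(>F)"]][1]
  }
  branch <- if (!is.na(normality_p) && !is.na(levene_p) &&
                normality_p > alpha && levene_p > alpha) {
    "parametric"
  } else {
    "nonparametric"
  }
  structure(list(normality_p = normality_p, levene_p = levene_p,
                 branch = branch,
                 insufficient_n = insufficient, constant_data = constant),
            class = "distribution_check")
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction, two-sided
#' normal p values; unadjusted by default (a Bonferroni option is
#' available).
#'
#' @param values,groups Observations and grouping factor.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return List with matrices `z` and `p` (groups x groups).
#' @export
dunn_test <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  k <- nlevels(groups)
  stopifnot(k >= 2)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  z <- p <- matrix(NA_real_, k, k,
                   dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    zz <- (rbar[i] - rbar[j]) / se
    z[i, j] <- z[j, i] <- zz
    p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(zz))
  }
  if (p_adjust != "none") {
    up <- p[upper.tri(p)]
    p[upper.tri(p)] <- stats::p.adjust(up, method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  list(z = z, p = p)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb construction: groups sharing a letter are not
#' significantly different. Deterministic for a given matrix (letter sets
#' are ordered by their first group).
#'
#' @param sig Logical k x k matrix, `TRUE` where the pair differs
#'   significantly; row/column names are the group labels.
#' @return Character vector of letter strings, one per group.
#' @export
compact_letters <- function(sig) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  k <- nrow(sig)
  sets <- list(seq_len(k))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (!isTRUE(sig[i, j])) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      new_sets <- new_sets[lengths(new_sets) > 0]
      # absorb sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
      sets <- new_sets[keep]
    }
  }
  ord <- order(vapply(sets, min, 0))
  sets <- sets[ord]
  out <- character(k)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  names(out) <- rownames(sig)
  out
}

#' Compare groups with the routed test and a letter display
#'
#' Parametric branch: one-way ANOVA with Tukey HSD pairwise comparisons.
#' Non-parametric branch: Kruskal-Wallis with Dunn's pairwise z tests
#' (unadjusted two-sided by default). The compact letter display is built
#' from the pairwise significance matrix at `alpha`.
#'
#' @param values,groups Observations and grouping factor (each group
#'   n >= 2).
#' @param branch `"auto"` routes via [check_distribution()]; or force
#'   `"parametric"` / `"nonparametric"`.
#' @param alpha Significance level for the letters.
#' @param p_adjust Adjustment for Dunn p values (`"none"` default).
#' @return Object of class `group_comparison`: per-group `summary` (n,
#'   mean, sd, median, iqr, cv_pct, letters), `test` (name, statistic, p),
#'   `pairwise_p` matrix, `branch`.
#' @export
compare_groups <- function(values, groups,
                           branch = c("auto", "parametric", "nonparametric"),
                           alpha = 0.05, p_adjust = "none") {
  branch <- match.arg(branch)
  groups <- factor(groups)
  if (any(tapply(values, groups, length) < 2)) {
    stop("every group needs at least 2 observations")
  }
  if (branch == "auto") {
    branch <- check_distribution(values, groups, alpha)$branch
  }
  if (branch == "parametric") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    k <- nlevels(groups)
    pw <- matrix(NA_real_, k, k,
                 dimnames = list(levels(groups), levels(groups)))
    for (rn in rownames(tk)) {
      gg <- strsplit(rn, "-", fixed = TRUE)[[1]]
      pw[gg[1], gg[2]] <- pw[gg[2], gg[1]] <- tk[rn, "p adj"]
    }
    test_name <- "ANOVA + Tukey HSD"
  } else {
    kw <- stats::kruskal.test(values ~ groups)
    statistic <- unname(kw$statistic)
    p <- kw$p.value
    pw <- dunn_test(values, groups, p_adjust)$p
    test_name <- "Kruskal-Wallis + Dunn"
  }
  sig <- !is.na(pw) & pw < alpha
  cld <- compact_letters(sig)
  iqr <- tapply(values, groups, stats::IQR)
  mn <- tapply(values, groups, mean)
  sdv <- tapply(values, groups, stats::sd)
  summ <- data.frame(
    group = levels(groups),
    n = as.integer(tapply(values, groups, length)),
    mean = as.numeric(mn), sd = as.numeric(sdv),
    median = as.numeric(tapply(values, groups, stats::median)),
    iqr = as.numeric(iqr),
    cv_pct = as.numeric(ifelse(mn == 0, NA, 100 * sdv / mn)),
    letters = unname(cld)
  )
  structure(list(summary = summ,
                 test = list(name = test_name, statistic = statistic, p = p),
                 pairwise_p = pw, branch = branch, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test$name, x$test$statistic, x$test$p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Correlation with Fisher-z confidence interval
#'
#' Pearson (default) or Spearman correlation; for Pearson the p value uses
#' `t = r sqrt(n-2) / sqrt(1-r^2)` with `n - 2` df and the 95 percent
#' interval is `tanh(atanh(r) +/- 1.96 / sqrt(n-3))`. Spearman applies the
#' same machinery to the ranks.
#'
#' @param x,y Paired observations (`n >= 4` for the interval).
#' @param method `"pearson"` or `"spearman"`.
#' @return Object of class `correlation_result`: `r`, `r_squared`, `ci`
#'   (length 2), `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations for the interval")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y")
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  ci <- tanh(atanh(r) + c(-1, 1) * 1.96 / sqrt(n - 3))
  structure(list(r = r, r_squared = r^2, ci = ci, p = p, n = n,
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s r = %.4f (R^2 = %.4f), 95%% CI %.4f to %.4f, p = %.4f, n = %d\n",
              x$method, x$r, x$r_squared, x$ci[1], x$ci[2], x$p, x$n))
  invisible(x)
}

#' Principal component analysis with the Kaiser criterion
#'
#' Columns are z-scored (sd with n - 1), the correlation matrix is
#' eigendecomposed, components are sorted by eigenvalue and retained when
#' the eigenvalue exceeds 1.0. Deterministic sign convention: the
#' largest-magnitude element of each loading vector is positive.
#'
#' @param x Numeric matrix or data frame (>= 3 rows, >= 2 columns, no
#'   missing values, no constant columns).
#' @return Object of class `pca_result`: `eigenvalues`, `var_pct`,
#'   `retained` (Kaiser indices), `loadings`, `scores`, `center`, `scale`.
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) stop("need >= 3 observations and >= 2 variables")
  if (anyNA(x)) stop("missing values are not allowed")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  load <- eg$vectors
  # sign convention
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  scores <- z %*% load
  structure(list(
    eigenvalues = eg$values,
    var_pct = 100 * eg$values / sum(eg$values),
    retained = which(eg$values > 1.0),
    loadings = load, scores = scores,
    center = attr(z, "scaled:center"), scale = attr(z, "scaled:scale"),
    n = nrow(x)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n  variance explained (%):",
      paste(sprintf("%.2f", x$var_pct[seq_len(min(5, length(x$var_pct)))]),
            collapse = ", "),
      sprintf("\n  Kaiser-retained components: %s\n",
              paste(x$retained, collapse = ", ")))
  invisible(x)
}
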