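# Statistical layer: omnibus normality test against an independent oracle,
# routing, group comparisons, letters, correlations, PCA.

test_that("omnibus normality statistic matches the independent oracle", {
  # frozen oracle values computed independently with scipy.stats.normaltest
  # on the same deterministic samples
  set.seed(424242)
  x <- round(stats::rnorm(30, 10, 2), 4)
  set.seed(777)
  y <- round(stats::rgamma(40, shape = 1.3, rate = 0.6), 4)
  rx <- dagostino_pearson(x)
  ry <- dagostino_pearson(y)
  expect_equal(rx$k2, 1.10215766, tolerance = 1e-7)
  expect_equal(rx$p, 0.57632772, tolerance = 1e-7)
  expect_equal(ry$k2, 6.07781811, tolerance = 1e-7)
  expect_equal(ry$p, 0.04788710, tolerance = 1e-7)
  expect_error(dagostino_pearson(1:5), "n >= 8")
})

test_that("routing uses pooled residual normality and Levene homogeneity", {
  g <- rep(c("a", "b"), each = 10)
  v <- c(1:10, 1:10)
  chk <- check_distribution(v, g)
  expect_equal(chk$levene_p, 1)           # identical spreads
  expect_false(chk$insufficient_n)
  # single group of 5: the omnibus test refuses with a flag
  chk5 <- check_distribution(c(5.1, 4.9, 5.0, 5.2, 4.8), rep("a", 5))
  expect_true(chk5$insufficient_n)
  expect_true(is.na(chk5$normality_p))
  expect_equal(chk5$branch, "nonparametric")
  # constant data flagged
  chkc <- check_distribution(rep(3, 10), rep(c("a", "b"), each = 5))
  expect_true(chkc$constant_data)
})

test_that("the omnibus test keeps its nominal size under the null", {
  reject <- vapply(1:100, function(s) {
    set.seed(s)
    dagostino_pearson(stats::rnorm(500))$p <= 0.05
  }, TRUE)
  expect_gte(mean(!reject), 0.90)
})

test_that("identical groups give null statistics and a shared letter", {
  v <- c(1, 2, 3, 1, 2, 3); g <- rep(c("a", "b"), each = 3)
  gc <- compare_groups(v, g, branch = "parametric")
  expect_equal(gc$test$statistic, 0)
  expect_equal(gc$test$p, 1)
  expect_equal(unique(gc$summary$letters), "a")
  kw <- compare_groups(v, g, branch = "nonparametric")
  expect_equal(kw$test$statistic, 0)
  expect_error(compare_groups(c(1, 1, 2), c("a", "a", "b")), "at least 2")
})

test_that("Dunn z statistics match the mean-rank formula without ties", {
  v <- c(1, 2, 3, 10, 11, 12); g <- rep(c("A", "B"), each = 3)
  d <- dunn_test(v, g)
  expect_equal(d$z["A", "B"], (2 - 5) / sqrt(6 * 7 / 12 * (2 / 3)))
  # Kruskal-Wallis H is invariant under monotone transforms
  k1 <- stats::kruskal.test(v, factor(g))$statistic
  k2 <- stats::kruskal.test(exp(v), factor(g))$statistic
  expect_equal(k1, k2)
  # Bonferroni option never lowers a p value
  db <- dunn_test(v, g, p_adjust = "bonferroni")
  expect_gte(db$p["A", "B"], d$p["A", "B"])
})

test_that("compact letters are consistent with the pairwise matrix", {
  # brute-force property over random significance patterns
  for (s in 1:25) {
    set.seed(s)
    k <- sample(3:6, 1)
    sig <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sig[i, j] <- sig[j, i] <- stats::runif(1) < 0.4
    }
    cl <- compact_letters(sig)
    share <- function(a, b) {
      any(strsplit(cl[a], "")[[1]] %in% strsplit(cl[b], "")[[1]])
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      expect_identical(share(i, j), !sig[i, j],
                       info = sprintf("seed %d pair %d-%d", s, i, j))
    }
  }
})

test_that("group simulation at the packaged body-weight set points separates the extremes", {
  sp <- default_cohort_setpoints()
  hits <- 0; sep66 <- 0; other_sep <- 0
  for (s in 1:200) {
    set.seed(s)
    v <- unlist(lapply(seq_len(5), function(i) {
      stats::rnorm(5, sp$bw_kg_mean[i], sp$bw_kg_sd[i])
    }))
    g <- factor(rep(sp$age_months, each = 5))
    gc <- compare_groups(v, g, branch = "parametric")
    if (gc$test$p < 0.05) hits <- hits + 1
    pw <- gc$pairwise_p
    if (!is.na(pw["6", "36"]) && pw["6", "36"] < 0.05) sep66 <- sep66 + 1
    others <- pw[upper.tri(pw)]
    other_sep <- other_sep + sum(others < 0.05, na.rm = TRUE)
  }
  expect_gt(hits, 100)                   # ANOVA rejects in the majority
  # the 6 vs 36 month pair is the most frequently separated pair
  expect_gte(sep66, (other_sep - sep66) / 9)
})

test_that("correlation handles the exact and antithetic cases", {
  x <- c(1, 2, 3, 4, 5)
  r1 <- correlate(x, x)
  expect_equal(r1$r, 1)
  expect_equal(r1$r_squared, 1)
  r2 <- correlate(x, -x)
  expect_equal(r2$r, -1)
  expect_error(correlate(1:3, 1:3), "at least 4")
  expect_error(correlate(x, rep(2, 5)), "zero variance")
  # R^2 = r^2 and the interval contains r
  r3 <- correlate(x, c(2, 1, 4, 3, 6))
  expect_equal(r3$r_squared, r3$r^2, tolerance = 1e-12)
  expect_true(r3$ci[1] <= r3$r && r3$r <= r3$ci[2])
  # Spearman is the Pearson correlation of the ranks
  r4 <- correlate(x, c(10, 30, 20, 50, 40), method = "spearman")
  expect_equal(r4$r, stats::cor(x, c(10, 30, 20, 50, 40),
                                method = "spearman"))
})

test_that("PCA standardises, retains by Kaiser, and fixes loading signs", {
  set.seed(9)
  a <- stats::rnorm(40)
  x <- cbind(v1 = a, v2 = 2 * a + 1e-8 * stats::rnorm(40),
             v3 = stats::rnorm(40))
  p <- run_pca(x)
  expect_equal(sum(p$var_pct), 100, tolerance = 1e-9)
  # two perfectly correlated variables dominate PC1
  p2 <- run_pca(cbind(u = a, w = 3 * a))
  expect_equal(p2$var_pct[1], 100, tolerance = 1e-6)
  # scores are centred
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
  # retained set matches the strict Kaiser rule
  expect_identical(p$retained, which(p$eigenvalues > 1))
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_error(run_pca(cbind(a, rep(1, 40))), "constant column")
  expect_error(run_pca(matrix(c(1, 2, NA, 4, 5, 6), 3)), "missing values")
})
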