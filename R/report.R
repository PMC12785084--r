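# Report layer: regenerates the study's three summary-table layouts and the
# PCA score/loading tables from cohort pipeline outputs.

#' Correlations of age with the macroscopic group means
#'
#' The age-correlation table is computed on the per-group means against the
#' group ages (n = number of groups), the convention under which printed
#' morphometric correlation tables of this design are reproducible, not on
#' the individual animals.
#'
#' @param animals Animal table with `age_months` and the variables.
#' @param variables Named character vector: table label -> column name.
#' @param method Correlation method (macroscopic variables are Pearson).
#' @return Data frame with `comparison`, `r`, `r_squared`, `ci_low`,
#'   `ci_high`, `p`, `n`, `interpretation`.
#' @export
age_correlation_table <- function(animals,
                                  variables = c(BW = "bw_kg", TW = "tw_g",
                                                `T-index` = "t_index",
                                                GSI = "gsi"),
                                  method = "pearson") {
  stopifnot("age_months" %in% names(animals))
  ages <- sort(unique(animals$age_months))
  rows <- lapply(seq_along(variables), function(i) {
    v <- variables[[i]]
    mns <- vapply(ages, function(a) {
      mean(animals[[v]][animals$age_months == a])
    }, 0)
    ct <- correlate(ages, mns, method = method)
    data.frame(
      comparison = paste0("Age vs. ", names(variables)[i]),
      r = ct$r, r_squared = ct$r_squared,
      ci_low = ct$ci[1], ci_high = ct$ci[2], p = ct$p, n = ct$n,
      interpretation = .interpret_r(ct$r, ct$p))
  })
  do.call(rbind, rows)
}

.interpret_r <- function(r, p, alpha = 0.05) {
  strength <- if (abs(r) >= 0.8) "strong" else if (abs(r) >= 0.5)
    "moderate" else "weak"
  direction <- if (r >= 0) "positive" else "negative"
  if (p < alpha) {
    sprintf("%s and significant %s correlation", strength, direction)
  } else {
    sprintf("%s %s correlation, not significant", strength, direction)
  }
}

#' Build the full report from cohort outputs
#'
#' Writes the three summary tables and the PCA tables as CSV plus a
#' human-readable `report.txt`: macroscopic morphometry as mean +/- SD
#' [CV%] with compact significance letters (ANOVA/Tukey branch), DAB
#' immunoreactivity as median (SD) with the Kruskal-Wallis p (Dunn
#' letters), the age-correlation table, and the PCA scores/loadings of the
#' stereological estimate matrix. Re-running on the same inputs reproduces
#' the files byte for byte.
#'
#' @param animals Cohort animal table (from [generate_cohort()]).
#' @param ihc An [run_ihc_pipeline()] result (or its `animals` table).
#' @param stereo An [run_stereology_pipeline()] result (optional; enables
#'   the PCA tables).
#' @param out_dir Output directory, created if missing.
#' @param alpha Significance level for letters.
#' @return Invisibly, the list of written file paths.
#' @export
build_report <- function(animals, ihc = NULL, stereo = NULL, out_dir,
                         alpha = 0.05) {
  if (is.null(animals) || nrow(animals) == 0) {
    stop("empty cohort: nothing to report")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  txt <- c("Cohort report", "=============", "")

  # --- macroscopic table (mean +/- SD [CV%], letters, p) ---
  vars <- c(`BW (kg)` = "bw_kg", `TW (g)` = "tw_g",
            `T-index` = "t_index", `GSI` = "gsi")
  grp <- factor(animals$age_months)
  t1 <- list()
  for (i in seq_along(vars)) {
    gc <- compare_groups(animals[[vars[[i]]]], grp, branch = "parametric",
                         alpha = alpha)
    s <- gc$summary
    row <- data.frame(variable = names(vars)[i])
    for (g in seq_len(nrow(s))) {
      row[[paste0("m", s$group[g])]] <-
        sprintf("%.3g %s ± %.3g[%.1f%%]", s$mean[g], s$letters[g],
                s$sd[g], s$cv_pct[g])
    }
    row$p_value <- signif(gc$test$p, 3)
    t1[[i]] <- row
  }
  t1 <- do.call(rbind, t1)
  p1 <- file.path(out_dir, "table1.csv")
  utils::write.csv(t1, p1, row.names = FALSE)
  paths <- c(paths, p1)
  txt <- c(txt, "Macroscopic morphometry (mean ± SD [CV%], ANOVA + Tukey letters):",
           utils::capture.output(print(t1, row.names = FALSE)), "")

  # --- IHC table (median (SD), Kruskal-Wallis) ---
  if (!is.null(ihc)) {
    it <- if (inherits(ihc, "ihc_cohort")) ihc$animals else ihc
    t2 <- list()
    for (v in c("ira", "iod")) {
      gc <- compare_groups(it[[v]], factor(it$age_months),
                           branch = "nonparametric", alpha = alpha)
      s <- gc$summary
      row <- data.frame(variable = toupper(v))
      for (g in seq_len(nrow(s))) {
        row[[paste0("m", s$group[g])]] <-
          sprintf("%.4g%s (%.3g)", s$median[g], s$letters[g], s$sd[g])
      }
      row$p_value <- signif(gc$test$p, 3)
      t2[[v]] <- row
    }
    t2 <- do.call(rbind, t2)
    p2 <- file.path(out_dir, "table2.csv")
    utils::write.csv(t2, p2, row.names = FALSE)
    paths <- c(paths, p2)
    txt <- c(txt, "DAB immunoreactivity (median (SD), Kruskal-Wallis + Dunn letters):",
             utils::capture.output(print(t2, row.names = FALSE)), "")
  }

  # --- age correlations ---
  t3 <- age_correlation_table(animals)
  p3 <- file.path(out_dir, "table3.csv")
  utils::write.csv(t3, p3, row.names = FALSE)
  paths <- c(paths, p3)
  txt <- c(txt, "Age correlations (Pearson on group means):",
           utils::capture.output(print(t3, row.names = FALSE)), "")

  # --- PCA of the stereological estimates ---
  if (!is.null(stereo)) {
    est <- if (inherits(stereo, "stereo_cohort")) stereo$estimates else stereo
    wide <- stereo_wide(est)
    pca <- run_pca(wide[, setdiff(names(wide),
                                  c("animal_id", "age_months"))])
    sc <- data.frame(animal_id = wide$animal_id,
                     age_months = wide$age_months,
                     pca$scores[, pca$retained, drop = FALSE])
    ld <- data.frame(variable = rownames(pca$loadings),
                     pca$loadings[, pca$retained, drop = FALSE],
                     row.names = NULL)
    p4 <- file.path(out_dir, "pca_scores.csv")
    p5 <- file.path(out_dir, "pca_loadings.csv")
    utils::write.csv(sc, p4, row.names = FALSE)
    utils::write.csv(ld, p5, row.names = FALSE)
    paths <- c(paths, p4, p5)
    txt <- c(txt, sprintf("PCA: retained %d components (Kaiser), variance %%: %s",
                          length(pca$retained),
                          paste(sprintf("%.2f", pca$var_pct[pca$retained]),
                                collapse = ", ")), "")
  }

  pt <- file.path(out_dir, "report.txt")
  writeLines(txt, pt)
  paths <- c(paths, pt)
  invisible(paths)
}

#' Age-correlation table from the packaged macroscopic set points
#'
#' Runs the correlation pipeline on the reference group means of the five
#' macroscopic variables (body weight, testis weight, right and left
#' testicular index, gonadosomatic index) against the group ages — the
#' desk-scale reproduction of the study's correlation table from its own
#' printed summary.
#'
#' @param setpoints A [default_cohort_setpoints()] table.
#' @return Data frame as in [age_correlation_table()].
#' @export
reference_correlation_table <- function(setpoints = default_cohort_setpoints()) {
  vars <- c(BW = "bw_kg_mean", TW = "tw_g_mean",
            `Right T-index` = "t_index_right_mean",
            `Left T-index` = "t_index_left_mean",
            GSI = "gsi_mean")
  rows <- lapply(seq_along(vars), function(i) {
    ct <- correlate(setpoints$age_months, setpoints[[vars[[i]]]])
    data.frame(comparison = paste0("Age vs. ", names(vars)[i]),
               r = ct$r, r_squared = ct$r_squared,
               ci_low = ct$ci[1], ci_high = ct$ci[2], p = ct$p, n = ct$n,
               interpretation = .interpret_r(ct$r, ct$p))
  })
  do.call(rbind, rows)
}

#' Pivot the long stereology estimate table to one row per animal
#'
#' @param estimates The `estimates` table of [run_stereology_pipeline()].
#' @return Wide data frame, one column per estimator/name pair.
#' @export
stereo_wide <- function(estimates) {
  key <- paste(estimates$estimator, estimates$name, sep = "_")
  ids <- unique(estimates[, c("animal_id", "age_months")])
  wide <- ids
  for (k in unique(key)) {
    sub <- estimates[key == k, c("animal_id", "value")]
    wide[[k]] <- sub$value[match(wide$animal_id, sub$animal_id)]
  }
  wide
}
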