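# Cohort-level simulation: per-age-group parameter sets (the packaged
# defaults emulate a postnatal maturation series of the domestic cat testis
# across 6, 8, 12, 24 and 36 months, n = 5 per group), reproducible animal
# tables, and per-animal field seed streams.

# deterministic sub-seed stream, kept below 2^31
.derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master %% 2147483647)
  for (k in idx) s <- (s * 48271 + k * 9973 + 1) %% 2147483647
  as.integer(s)
}

# truncated-normal-at-zero draw (all morphometric quantities are positive)
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out <= 0
  guard <- 0
  while (any(bad) && guard < 1000) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out <= 0
    guard <- guard + 1
  }
  if (any(bad)) stop("truncated-normal sampling failed")
  out
}

#' Packaged per-age-group set points
#'
#' The default study conditions: group means and SDs of the macroscopic
#' variables, microscopic reference volumes, tissue-architecture parameters
#' and DAB immunostaining set points for the five postnatal age groups
#' (6, 8, 12, 24, 36 months). These are the ground-truth values the cohort
#' generator draws from and the recovery targets of the estimation
#' pipeline.
#'
#' @return Data frame with one row per age group.
#' @export
default_cohort_setpoints <- function() {
  data.frame(
    age_months = c(6, 8, 12, 24, 36),
    bw_kg_mean = c(2.58, 3.02, 3.30, 3.58, 3.91),
    bw_kg_sd = c(0.476, 0.46, 0.367, 0.39, 0.619),
    tw_g_mean = c(36.3, 69.2, 60.4, 66.5, 63.5),
    tw_g_sd = c(7.71, 12.8, 13.2, 10.6, 12.7),
    # reference group means of the derived macroscopic indices
    t_index_right_mean = c(39, 70, 69.9, 66.4, 65.3),
    t_index_left_mean = c(35.8, 67.8, 59, 64.6, 61.1),
    gsi_mean = c(36, 90.8, 86.5, 104, 130),
    # linear dimensions chosen so that length x width (mm) / BW (kg)
    # reproduces the T-index means; width = 0.7 x length, height = width
    length_cm_mean = c(1.199, 1.738, 1.816, 1.843, 1.910),
    width_cm_mean = c(0.839, 1.217, 1.271, 1.290, 1.337),
    dim_cv = 0.08,
    vol_ref_mm3 = c(0.34, 0.80, 1.30, 1.80, 2.15),
    vol_ref_cv = 0.10,
    tubule_radius_mean = c(60, 68, 72, 74, 75),
    lumen_fraction = c(0.140, 0.200, 0.220, 0.240, 0.248),
    target_tubule_area_fraction = c(0.40, 0.44, 0.45, 0.46, 0.47),
    sertoli_density = c(280, 285, 290, 290, 285),
    germ_density = c(5000, 5400, 5600, 5500, 5400),
    leydig_density = 900,
    ira_fraction = c(0.18170, 0.09877, 0.09183, 0.07185, 0.03084),
    dab_od_mean = c(0.7442, 0.6397, 0.5605, 0.5153, 0.2452),
    dab_od_sd = c(0.028, 0.020, 0.040, 0.020, 0.027)
  )
}

#' Cohort configuration
#'
#' Bundles the per-group set points with the sampling design: animals per
#' group, stereology fields per testis (5 fields x 2 regions x 5 sections
#' by default), IHC fields per animal, grid unit and field size.
#'
#' @param setpoints Per-group set-point table
#'   (default [default_cohort_setpoints()]).
#' @param n_per_group Animals per age group (>= 2).
#' @param fields_per_testis Stereology fields per animal.
#' @param ihc_fields_per_animal DAB fields per animal.
#' @param field_size Field side length, micrometres.
#' @param grid_d M36 grid unit, micrometres (the default makes the 6 x 6
#'   lattice tile the field exactly).
#' @param master_seed Master seed; the whole cohort is a pure function of
#'   `(config, master_seed)`.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(setpoints = default_cohort_setpoints(),
                          n_per_group = 5,
                          fields_per_testis = 50,
                          ihc_fields_per_animal = 5,
                          field_size = 600,
                          grid_d = field_size / 6,
                          master_seed = 20260101) {
  stopifnot(n_per_group >= 2, fields_per_testis >= 1,
            ihc_fields_per_animal >= 1, field_size > 0, grid_d > 0,
            all(setpoints$bw_kg_sd >= 0), all(setpoints$tw_g_sd >= 0))
  structure(list(
    setpoints = setpoints, n_per_group = n_per_group,
    fields_per_testis = fields_per_testis,
    ihc_fields_per_animal = ihc_fields_per_animal,
    field_size = field_size, grid_d = grid_d,
    master_seed = master_seed
  ), class = "cohort_config")
}

#' Tissue parameters of one age group
#'
#' @param cfg A [cohort_config()].
#' @param age_months One of the configured ages.
#' @return A [tissue_params()] object.
#' @export
group_tissue_params <- function(cfg, age_months) {
  sp <- cfg$setpoints
  i <- match(age_months, sp$age_months)
  if (is.na(i)) stop("unknown age group: ", age_months)
  tissue_params(
    field_width = cfg$field_size, field_height = cfg$field_size,
    tubule_radius_mean = sp$tubule_radius_mean[i],
    tubule_radius_sd = 0.1 * sp$tubule_radius_mean[i],
    lumen_fraction = sp$lumen_fraction[i],
    target_tubule_area_fraction = sp$target_tubule_area_fraction[i],
    epithelium_cell_density = sp$germ_density[i],
    sertoli_density = sp$sertoli_density[i],
    leydig_density = sp$leydig_density[i]
  )
}

#' IHC synthesis parameters of one age group
#'
#' @inheritParams group_tissue_params
#' @return An [ihc_synth_params()] object.
#' @export
group_ihc_params <- function(cfg, age_months) {
  sp <- cfg$setpoints
  i <- match(age_months, sp$age_months)
  if (is.na(i)) stop("unknown age group: ", age_months)
  ihc_synth_params(
    positive_area_fraction_of_interstitium = sp$ira_fraction[i],
    dab_od_mean = sp$dab_od_mean[i],
    dab_od_sd = sp$dab_od_sd[i]
  )
}

#' Generate a cohort
#'
#' Draws the per-animal macroscopic variables (truncated normal at zero,
#' with the group means and SDs), assigns the per-animal microscopic
#' reference volume, derives the morphometric indices, and lays out the
#' per-field seed streams for the stereology and IHC pipelines. Byte-level
#' reproducible from `(config, master_seed)`.
#'
#' @param cfg A [cohort_config()].
#' @return Object of class `cohort`: `animals` data frame (`animal_id`,
#'   `age_months`, `bw_kg`, `tw_g`, `length_cm`, `width_cm`, `height_cm`,
#'   `fresh_volume_cm3`, `displaced_mass_g`, `vol_ref_mm3`, `t_index`,
#'   `gsi`) and the `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(.derive_seed(cfg$master_seed, 1))
  sp <- cfg$setpoints
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    n <- cfg$n_per_group
    bw <- .rtruncnorm0(n, sp$bw_kg_mean[i], sp$bw_kg_sd[i])
    tw <- .rtruncnorm0(n, sp$tw_g_mean[i], sp$tw_g_sd[i])
    len <- .rtruncnorm0(n, sp$length_cm_mean[i],
                        sp$dim_cv[i] * sp$length_cm_mean[i])
    wid <- .rtruncnorm0(n, sp$width_cm_mean[i],
                        sp$dim_cv[i] * sp$width_cm_mean[i])
    hei <- .rtruncnorm0(n, sp$width_cm_mean[i],
                        sp$dim_cv[i] * sp$width_cm_mean[i])
    vref <- .rtruncnorm0(n, sp$vol_ref_mm3[i],
                         sp$vol_ref_cv[i] * sp$vol_ref_mm3[i])
    vol <- pi / 6 * len * wid * hei      # ellipsoid, cm^3
    rows[[i]] <- data.frame(
      animal_id = sprintf("m%02d_%02d", sp$age_months[i], seq_len(n)),
      age_months = sp$age_months[i],
      bw_kg = bw, tw_g = tw,
      length_cm = len, width_cm = wid, height_cm = hei,
      fresh_volume_cm3 = vol,
      displaced_mass_g = vol * 1.0048,
      vol_ref_mm3 = vref
    )
  }
  animals <- derive_indices(do.call(rbind, rows))
  structure(list(animals = animals, config = cfg), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d animals in %d age groups (%s months), %d stereology + %d IHC fields per animal\n",
              nrow(x$animals), length(unique(x$animals$age_months)),
              paste(sort(unique(x$animals$age_months)), collapse = ", "),
              x$config$fields_per_testis, x$config$ihc_fields_per_animal))
  invisible(x)
}

#' Write a cohort's animal table and manifest
#'
#' `animals.csv` holds the per-animal table; `manifest.json` records
#' everything needed to regenerate the cohort and its fields exactly: the
#' master seed, the sampling design, the per-group set points and the stain
#' colour matrix used for DAB synthesis.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "animals.csv")
  utils::write.csv(cohort$animals, path, row.names = FALSE)
  cfg <- cohort$config
  manifest <- list(
    master_seed = cfg$master_seed,
    n_per_group = cfg$n_per_group,
    fields_per_testis = cfg$fields_per_testis,
    ihc_fields_per_animal = cfg$ihc_fields_per_animal,
    field_size_um = cfg$field_size,
    grid_d_um = cfg$grid_d,
    stain_matrix = hdab_stain_matrix(),
    setpoints = cfg$setpoints
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, mpath))
}

#' Run the stereological estimation pipeline on a cohort
#'
#' For every animal: generates `fields_per_testis` synthetic fields from its
#' group's tissue parameters, counts each with a freshly randomised M36
#' grid, pools the counts into the V_V, S_V and Q_A estimators, estimates
#' the reference volume by Cavalieri sampling of an ellipsoid phantom of the
#' animal's true reference volume (slab interval set to an eighth of the
#' phantom height so the series has 8-9 slabs), applies the
#' uniform-shrinkage reference-volume convention, and forms the absolute
#' compartment volumes with propagated CEs. Also records the pooled analytic
#' ground truth of the generated fields.
#'
#' @param cohort A [generate_cohort()] result.
#' @param fields_per_testis Override the configured field count.
#' @param progress Print one line per animal.
#' @return Object of class `stereo_cohort`: `estimates` (long data frame:
#'   `animal_id`, `age_months`, `estimator`, `name`, `value`, `units`,
#'   `ce`), `truth` (pooled analytic ground truth per animal), `config`.
#' @export
run_stereology_pipeline <- function(cohort,
                                    fields_per_testis = NULL,
                                    progress = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  cfg <- cohort$config
  nf <- if (is.null(fields_per_testis)) cfg$fields_per_testis else
    fields_per_testis
  est_rows <- list()
  truth_rows <- list()
  for (ai in seq_len(nrow(cohort$animals))) {
    an <- cohort$animals[ai, ]
    tp <- group_tissue_params(cfg, an$age_months)
    recs <- vector("list", nf)
    aa <- matrix(0, nf, 3); ba <- numeric(nf); na_ <- matrix(0, nf, 3)
    for (f in seq_len(nf)) {
      gseed <- .derive_seed(cfg$master_seed, 2, ai, f)
      geom <- generate_geometry(tp, gseed)
      grid <- build_grid(cfg$grid_d, .derive_seed(cfg$master_seed, 3, ai, f))
      recs[[f]] <- count_field(geom, grid)
      gt <- analytic_ground_truth(geom)
      aa[f, ] <- gt$A_A; ba[f] <- gt$B_A; na_[f, ] <- gt$N_A
    }
    vv <- estimate_vv(recs)
    sv <- estimate_sv(recs)
    qa <- estimate_qa(recs)
    # Cavalieri reference volume on an ellipsoid phantom (a = b, c = 1.25 a)
    set.seed(.derive_seed(cfg$master_seed, 4, ai))
    a_ax <- (3 * an$vol_ref_mm3 / (4 * pi * 1.25))^(1 / 3)
    c_ax <- 1.25 * a_ax
    t_slab <- 2 * c_ax / 8
    slabs <- ellipsoid_slab_areas(c(a_ax, a_ax, c_ax), t_slab,
                                  stats::runif(1, 0, t_slab))
    cav <- cavalieri_volume(slabs, t_slab)
    vol_ref <- correct_reference_volume(cav$volume, .no_shrinkage())
    rows <- list(
      data.frame(estimator = "vv", name = vv$compartment,
                 value = vv$vv_pct, units = "%", ce = vv$ce),
      data.frame(estimator = "sv", name = "tubule",
                 value = sv$sv, units = "1/mm", ce = sv$ce),
      data.frame(estimator = "qa", name = qa$class,
                 value = qa$qa, units = "1/mm^2", ce = qa$ce),
      data.frame(estimator = "vol_ref", name = "testis",
                 value = as.numeric(vol_ref), units = "mm^3", ce = cav$ce)
    )
    vabs <- mapply(function(v, ce) {
      av <- absolute_volume(v / 100, as.numeric(vol_ref), ce, cav$ce)
      c(av$v_abs, av$ce)
    }, vv$vv_pct, vv$ce)
    rows$vabs <- data.frame(estimator = "v_abs", name = vv$compartment,
                            value = vabs[1, ], units = "mm^3",
                            ce = vabs[2, ])
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res <- cbind(animal_id = an$animal_id, age_months = an$age_months, res)
    est_rows[[ai]] <- res
    truth_rows[[ai]] <- data.frame(
      animal_id = an$animal_id, age_months = an$age_months,
      aa_epithelium = mean(aa[, 1]), aa_lumen = mean(aa[, 2]),
      aa_interstitium = mean(aa[, 3]), b_a = mean(ba),
      na_leydig = mean(na_[, 1]), na_sertoli = mean(na_[, 2]),
      na_germ = mean(na_[, 3]))
    if (progress) {
      message(sprintf("animal %s done (%d fields)", an$animal_id, nf))
    }
  }
  structure(list(estimates = do.call(rbind, est_rows),
                 truth = do.call(rbind, truth_rows),
                 config = cfg),
            class = "stereo_cohort")
}

# identity shrinkage (fresh = processed); the reference-volume convention
# then leaves the Cavalieri volume untouched
.no_shrinkage <- function() {
  compute_shrinkage(c(1, 1, 1), c(1, 1, 1), 50, 10)
}

#' Run the DAB quantification pipeline on a cohort
#'
#' For every animal: synthesises `ihc_fields_per_animal` DAB fields from the
#' group's tissue and staining parameters, pushes each through the
#' quantification chain (OD transform, colour deconvolution, fixed
#' threshold), and averages the five fields per animal.
#'
#' @param cohort A [generate_cohort()] result.
#' @param threshold Study-wide DAB OD threshold.
#' @param ages Subset of age groups to process (default all).
#' @param progress Print one line per animal.
#' @return Object of class `ihc_cohort`: `animals` data frame (`animal_id`,
#'   `age_months`, `ira`, `iod`), `fields` (per-field rows), `threshold`.
#' @export
run_ihc_pipeline <- function(cohort, threshold = calibrate_dab_threshold(),
                             ages = NULL, progress = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  cfg <- cohort$config
  animals <- cohort$animals
  if (!is.null(ages)) animals <- animals[animals$age_months %in% ages, ]
  if (nrow(animals) == 0) stop("no animals selected")
  out <- list(); fld <- list()
  for (ai in seq_len(nrow(animals))) {
    an <- animals[ai, ]
    tp <- group_tissue_params(cfg, an$age_months)
    ip <- group_ihc_params(cfg, an$age_months)
    idx <- match(an$animal_id, cohort$animals$animal_id)
    fres <- vector("list", cfg$ihc_fields_per_animal)
    for (f in seq_len(cfg$ihc_fields_per_animal)) {
      geom <- generate_geometry(tp, .derive_seed(cfg$master_seed, 5, idx, f))
      field <- synthesize_ihc_field(geom, ip,
                                    .derive_seed(cfg$master_seed, 6, idx, f))
      fres[[f]] <- quantify_ihc_field(field, threshold)
      fld[[length(fld) + 1]] <- data.frame(
        animal_id = an$animal_id, age_months = an$age_months, field = f,
        ira = fres[[f]]$ira, iod = fres[[f]]$iod)
    }
    agg <- aggregate_animal(fres)
    out[[ai]] <- data.frame(animal_id = an$animal_id,
                            age_months = an$age_months,
                            ira = agg$ira, iod = agg$iod)
    if (progress) message(sprintf("animal %s done", an$animal_id))
  }
  structure(list(animals = do.call(rbind, out),
                 fields = do.call(rbind, fld),
                 threshold = threshold),
            class = "ihc_cohort")
}
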