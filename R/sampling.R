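# Physical sampling chain: isotropic uniform random (IUR) orientation via the
# orientator, Cavalieri slab-series volume with its error coefficient,
# systematic uniform random (SURS) field placement, and shrinkage /
# section-thickness corrections.

#' Draw orientator angles for an IUR section
#'
#' First cut: a circle with 10 equal divisions gives the azimuth phi
#' (division drawn uniformly, reported at the division midpoint). Second cut:
#' a circle with 10 cosine-weighted divisions gives the colatitude theta; the
#' class boundaries are `theta_k = acos(1 - k/10)`, so that `cos(theta)` is
#' uniform on `[0, 1]`. The reported `theta` is drawn uniformly in cos-space
#' within its class (hence exactly cosine-weighted); the class index and the
#' class midpoint are returned alongside.
#'
#' @param seed Integer seed.
#' @return Object of class `orientator_angles` with `phi` (degrees),
#'   `phi_class` (0-9), `theta` (degrees), `theta_class` (0-9),
#'   `theta_class_midpoint` (degrees, midpoint in cos-space).
#' @export
draw_orientator_angles <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  kphi <- sample.int(10L, 1) - 1L
  phi <- 36 * kphi + 18
  kth <- sample.int(10L, 1) - 1L
  u <- stats::runif(1, 1 - (kth + 1) / 10, 1 - kth / 10)  # cos(theta) ~ U within class
  structure(list(
    phi = phi, phi_class = kphi,
    theta = acos(u) * 180 / pi,
    theta_class = kth,
    theta_class_midpoint = acos(1 - (kth + 0.5) / 10) * 180 / pi
  ), class = "orientator_angles")
}

#' Boundary of an orientator theta class
#'
#' `acos(1 - k/10)` in degrees; class 0 starts at 0 degrees and class 10's
#' upper boundary is 90 degrees.
#'
#' @param k Class boundary index in `0:10`.
#' @export
orientator_theta_boundary <- function(k) {
  stopifnot(all(k >= 0), all(k <= 10))
  acos(1 - k / 10) * 180 / pi
}

#' Cavalieri volume from a slab series
#'
#' `V = t * sum(a_i)` for slab interval `t` and slab cross-section areas
#' `a_i`, unbiased under a uniformly random start. The error coefficient uses
#' the Gundersen-Jensen smoothness-class m = 1 form with end-corrected
#' covariogram terms, `CE = sqrt(max(0, 3A + C' - 4B') / 240) / sum(a_i)`
#' where `A = sum(a_i^2)`, `B' = n/(n-1) * sum(a_i a_{i+1})`,
#' `C' = n/(n-2) * sum(a_i a_{i+2})`; the radicand is clipped at zero, so a
#' constant series reports CE = 0.
#'
#' @param slab_areas Slab areas (mm^2), at least 3.
#' @param t Slab interval (mm).
#' @return Object of class `cavalieri_estimate`: `volume` (mm^3), `ce`
#'   (relative), `n_slabs`.
#' @export
cavalieri_volume <- function(slab_areas, t) {
  stopifnot(t > 0, all(slab_areas >= 0))
  n <- length(slab_areas)
  if (n < 3) stop("Cavalieri estimation needs at least 3 slabs")
  a <- slab_areas
  S <- sum(a)
  A <- sum(a^2)
  B <- sum(a[-n] * a[-1]) * n / (n - 1)
  C <- sum(a[seq_len(n - 2)] * a[-(1:2)]) * n / (n - 2)
  rad <- (3 * A + C - 4 * B) / 240
  ce <- if (S > 0) sqrt(max(rad, 0)) / S else 0
  structure(list(volume = t * S, ce = ce, n_slabs = n, t = t),
            class = "cavalieri_estimate")
}

#' @export
print.cavalieri_estimate <- function(x, ...) {
  cat(sprintf("<cavalieri_estimate> V = %.4f mm^3 from %d slabs (t = %g mm), CE = %.3f%%\n",
              x$volume, x$n_slabs, x$t, 100 * x$ce))
  invisible(x)
}

#' Slab areas of an ellipsoid phantom under Cavalieri sampling
#'
#' Cross-section areas of an axis-aligned ellipsoid with semi-axes
#' `(a, b, c)` sliced perpendicular to the c-axis at positions
#' `-c + offset + k t`; used to exercise the Cavalieri estimator on bodies of
#' known volume.
#'
#' @param semi_axes Numeric length-3 `(a, b, c)` in mm.
#' @param t Slab interval (mm).
#' @param offset Random start in `[0, t)`.
#' @return Numeric vector of slab areas (mm^2), possibly of length 0.
#' @export
ellipsoid_slab_areas <- function(semi_axes, t, offset) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), t > 0,
            offset >= 0, offset < t)
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  z <- seq(-cc + offset, cc, by = t)
  if (!length(z)) return(numeric(0))
  pi * a * b * pmax(1 - (z / cc)^2, 0)
}

#' Plan systematic uniform random field positions on a section
#'
#' Fields are placed on a regular `nx x ny` lattice (a divisor pair of
#' `n_fields` chosen to make the steps as square as possible) with a uniform
#' random start inside one lattice cell, so that every point of the section
#' is covered with equal probability.
#'
#' @param bounds Numeric `(width, height)` of the section, micrometres.
#' @param n_fields Number of fields.
#' @param seed Integer seed.
#' @return Object of class `field_plan`: data frame of positions `x`, `y`
#'   plus the steps and random start used.
#' @export
plan_surs_fields <- function(bounds, n_fields, seed) {
  stopifnot(length(bounds) == 2, all(bounds > 0), n_fields >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # divisor pair nx * ny = n_fields with step aspect closest to the section's
  divs <- which(n_fields %% seq_len(n_fields) == 0)
  best <- NULL; best_score <- Inf
  for (nx in divs) {
    ny <- n_fields / nx
    score <- abs(log((bounds[1] / nx) / (bounds[2] / ny)))
    if (score < best_score) { best_score <- score; best <- c(nx, ny) }
  }
  nx <- best[1]; ny <- best[2]
  sx <- bounds[1] / nx; sy <- bounds[2] / ny
  ox <- stats::runif(1, 0, sx); oy <- stats::runif(1, 0, sy)
  pos <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  structure(list(
    positions = data.frame(x = ox + pos$ix * sx, y = oy + pos$iy * sy),
    step = c(sx, sy), start = c(ox, oy), bounds = bounds, seed = seed
  ), class = "field_plan")
}

#' Shrinkage factors from fresh vs processed dimensions
#'
#' The linear shrinkage coefficient `f_L` is the geometric mean of the
#' per-axis processed/fresh ratios; the area and volume factors are derived
#' as `f_A = f_L^2`, `f_V = f_L^3` (never set independently). The real
#' section thickness is the calibrated block advance divided by the number
#' of sections cut. A deformation index (post-embedding area over
#' pre-sectioning area) may be supplied and is carried through.
#'
#' @param fresh_dims,processed_dims Matching positive dimension vectors.
#' @param block_height_change Total block advance (micrometres).
#' @param n_sections Number of sections cut during that advance.
#' @param deformation_index Optional area deformation index.
#' @return Object of class `shrinkage_factors` with `f_L`, `f_A`, `f_V`,
#'   `t_real` (micrometres) and `deformation_index`.
#' @export
compute_shrinkage <- function(fresh_dims, processed_dims,
                              block_height_change, n_sections,
                              deformation_index = NA_real_) {
  if (length(fresh_dims) != length(processed_dims)) {
    stop("fresh and processed dimension vectors must have the same length")
  }
  stopifnot(all(fresh_dims > 0), all(processed_dims > 0),
            block_height_change > 0, n_sections > 0)
  f_L <- exp(mean(log(processed_dims / fresh_dims)))
  if (f_L > 1.2) stop(sprintf("implausible linear factor %.3f (> 1.2)", f_L))
  structure(list(
    f_L = f_L, f_A = f_L^2, f_V = f_L^3,
    swelling = f_L > 1,
    t_real = block_height_change / n_sections,
    deformation_index = deformation_index
  ), class = "shrinkage_factors")
}

#' @export
print.shrinkage_factors <- function(x, ...) {
  cat(sprintf("<shrinkage_factors> f_L = %.4f (f_A = %.4f, f_V = %.4f), t_real = %.2f um%s\n",
              x$f_L, x$f_A, x$f_V, x$t_real,
              if (isTRUE(x$swelling)) " [swelling]" else ""))
  invisible(x)
}

#' Shrinkage factor from a trocar punch specimen
#'
#' A thin disk of known fresh diameter is punched from a slab; its processed
#' diameter directly yields the linear shrinkage coefficient.
#'
#' @param fresh_diameter,processed_diameter Punch diameters (same units).
#' @inheritParams compute_shrinkage
#' @export
punch_shrinkage <- function(fresh_diameter, processed_diameter,
                            block_height_change, n_sections) {
  compute_shrinkage(c(fresh_diameter, fresh_diameter),
                    c(processed_diameter, processed_diameter),
                    block_height_change, n_sections)
}

#' Corrected reference volume
#'
#' Two logged conventions. `"uniform-shrinkage"` (default): volume densities
#' measured on uniformly shrunken tissue are shrinkage-invariant (numerator
#' and denominator shrink together), so the reference volume for absolute
#' volumes is the fresh volume itself. `"processed"`: a processed-block
#' volume is inflated back to fresh scale by dividing by `f_V`.
#'
#' @param volume Input volume (mm^3): fresh volume for the default mode,
#'   processed-block volume for `"processed"`.
#' @param factors A [compute_shrinkage()] result.
#' @param mode `"uniform-shrinkage"` or `"processed"`.
#' @return Corrected reference volume (mm^3) with attribute `mode`.
#' @export
correct_reference_volume <- function(volume, factors,
                                     mode = c("uniform-shrinkage",
                                              "processed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(factors, "shrinkage_factors"), volume >= 0)
  if (factors$f_V <= 0) stop("f_V must be positive")
  out <- switch(mode,
                "uniform-shrinkage" = volume,
                "processed" = volume / factors$f_V)
  attr(out, "mode") <- mode
  attr(out, "f_V") <- factors$f_V
  out
}
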