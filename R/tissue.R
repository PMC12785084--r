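# Synthetic testis cross-section fields with analytic ground truth.
#
# A field is a rectangle of interstitium into which circular seminiferous
# tubule profiles (epithelium annulus + lumen) are packed by random sequential
# adsorption, plus circular cell profiles: Leydig cells in the interstitium,
# Sertoli and germ cells inside the epithelium annuli. All ground-truth
# quantities (area fractions, boundary length density, profile densities) are
# computed exactly from the circles, never from a raster.

#' Parameters of a synthetic tissue field
#'
#' @param field_width,field_height Field size in micrometres.
#' @param tubule_radius_mean,tubule_radius_sd Outer tubule radius distribution
#'   (truncated normal, micrometres).
#' @param lumen_fraction Lumen area as a fraction of the tubule profile area,
#'   in `[0, 1)`. The lumen radius is `outer_radius * sqrt(lumen_fraction)`.
#' @param target_tubule_area_fraction Target fraction of the field covered by
#'   tubule profiles, in `(0, 1)` (or 0 for a tubule-free field). Packing must
#'   land within 10 percent (relative) of this target or generation fails.
#' @param epithelium_cell_density Germ-cell profiles per mm^2 of epithelium.
#' @param sertoli_density Sertoli profiles per mm^2 of epithelium.
#' @param leydig_density Leydig profiles per mm^2 of interstitium.
#' @param cell_radius Named numeric: profile radius in micrometres for
#'   `leydig`, `sertoli`, `germ`.
#' @param min_separation Minimum clearance between tubule profiles
#'   (micrometres).
#' @return An object of class `tissue_params` (a validated list).
#' @export
tissue_params <- function(field_width = 600, field_height = 600,
                          tubule_radius_mean = 75, tubule_radius_sd = 7.5,
                          lumen_fraction = 0.25,
                          target_tubule_area_fraction = 0.45,
                          epithelium_cell_density = 5400,
                          sertoli_density = 290,
                          leydig_density = 900,
                          cell_radius = c(leydig = 9, sertoli = 17, germ = 3),
                          min_separation = 8) {
  stopifnot(field_width > 0, field_height > 0,
            tubule_radius_mean > 0, tubule_radius_sd >= 0,
            lumen_fraction >= 0, lumen_fraction < 1,
            target_tubule_area_fraction >= 0, target_tubule_area_fraction < 1,
            epithelium_cell_density >= 0, sertoli_density >= 0,
            leydig_density >= 0, min_separation >= 0,
            all(c("leydig", "sertoli", "germ") %in% names(cell_radius)),
            all(cell_radius > 0))
  structure(list(
    field_width = field_width, field_height = field_height,
    tubule_radius_mean = tubule_radius_mean,
    tubule_radius_sd = tubule_radius_sd,
    lumen_fraction = lumen_fraction,
    target_tubule_area_fraction = target_tubule_area_fraction,
    epithelium_cell_density = epithelium_cell_density,
    sertoli_density = sertoli_density,
    leydig_density = leydig_density,
    cell_radius = cell_radius,
    min_separation = min_separation
  ), class = "tissue_params")
}

#' Generate one synthetic tissue field
#'
#' Tubule profiles are packed by dart throwing (random sequential adsorption)
#' until the clipped tubule area reaches the target fraction; cells are then
#' placed by rejection sampling inside their host compartment. Leydig profiles
#' are mutually non-overlapping and lie wholly outside every tubule; Sertoli
#' and germ profiles lie wholly inside an epithelium annulus (profiles of
#' different epithelial cells may overlap, as nuclei in a packed epithelium
#' do). Deterministic for a fixed `(params, seed)` pair.
#'
#' @param params A [tissue_params()] object.
#' @param seed Integer seed.
#' @param max_attempts Dart-throwing budget for tubule packing.
#' @return An object of class `tissue_geometry`: field bounds, tubule table
#'   (`x`, `y`, `outer_r`, `lumen_r`), cell table (`x`, `y`, `r`, `class`),
#'   the achieved tubule area fraction and the seed used.
#' @export
generate_geometry <- function(params, seed, max_attempts = 8000) {
  stopifnot(inherits(params, "tissue_params"), is.numeric(seed))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  W <- params$field_width; H <- params$field_height
  A <- W * H
  target <- params$target_tubule_area_fraction * A

  tub <- data.frame(x = numeric(0), y = numeric(0),
                    outer_r = numeric(0), lumen_r = numeric(0))
  achieved <- 0
  if (target > 0) {
    attempts <- 0
    rmin <- max(params$tubule_radius_mean - 3 * params$tubule_radius_sd,
                0.2 * params$tubule_radius_mean)
    rmax <- params$tubule_radius_mean + 3 * params$tubule_radius_sd
    while (achieved < 0.95 * target && attempts < max_attempts) {
      attempts <- attempts + 1
      r <- stats::rnorm(1, params$tubule_radius_mean, params$tubule_radius_sd)
      if (r < rmin || r > rmax) next
      x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
      if (nrow(tub) > 0) {
        d2 <- (tub$x - x)^2 + (tub$y - y)^2
        if (any(d2 < (tub$outer_r + r + params$min_separation)^2)) next
      }
      a_new <- disk_rect_area(x, y, r, 0, 0, W, H)
      if (achieved + a_new > 1.10 * target) next
      tub <- rbind(tub, data.frame(x = x, y = y, outer_r = r,
                                   lumen_r = r * sqrt(params$lumen_fraction)))
      achieved <- achieved + a_new
    }
    if (abs(achieved / target - 1) > 0.10) {
      stop(sprintf(
        "tubule packing failed: achieved area fraction %.4f vs target %.4f",
        achieved / A, params$target_tubule_area_fraction))
    }
  }

  # host-compartment areas (clipped, exact)
  outer_areas <- if (nrow(tub)) mapply(disk_rect_area, tub$x, tub$y,
                                       tub$outer_r, 0, 0, W, H) else numeric(0)
  lumen_areas <- if (nrow(tub)) mapply(function(x, y, r) {
    if (r > 0) disk_rect_area(x, y, r, 0, 0, W, H) else 0
  }, tub$x, tub$y, tub$lumen_r) else numeric(0)
  epi_areas <- outer_areas - lumen_areas
  A_epi <- sum(epi_areas)
  A_int <- A - sum(outer_areas)

  cells <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                      class = character(0))
  um2_per_mm2 <- 1e6
  # epithelial classes: tubule chosen proportional to clipped epithelium area
  for (cls in c("sertoli", "germ")) {
    dens <- if (cls == "sertoli") params$sertoli_density else
      params$epithelium_cell_density
    n <- round(dens * A_epi / um2_per_mm2)
    if (n > 0 && nrow(tub) > 0) {
      cr <- params$cell_radius[[cls]]
      fits <- tub$outer_r - tub$lumen_r >= 2 * cr
      if (!any(fits)) stop(sprintf(
        "no tubule annulus is wide enough for %s profiles (r = %g)", cls, cr))
      w <- epi_areas * fits
      placed <- 0; guard <- 0
      xs <- numeric(n); ys <- numeric(n)
      while (placed < n && guard < 200 * n) {
        guard <- guard + 1
        ti <- sample.int(nrow(tub), 1, prob = w)
        lo2 <- (tub$lumen_r[ti] + cr)^2; hi2 <- (tub$outer_r[ti] - cr)^2
        rho <- sqrt(stats::runif(1, lo2, hi2))
        th <- stats::runif(1, 0, 2 * pi)
        cx <- tub$x[ti] + rho * cos(th); cy <- tub$y[ti] + rho * sin(th)
        if (cx < 0 || cx > W || cy < 0 || cy > H) next
        placed <- placed + 1
        xs[placed] <- cx; ys[placed] <- cy
      }
      if (placed < n) stop(sprintf("could not place all %s profiles", cls))
      cells <- rbind(cells, data.frame(x = xs, y = ys, r = cr, class = cls))
    }
  }
  # Leydig: wholly in interstitium (outside every tubule), non-overlapping
  n_ley <- round(params$leydig_density * A_int / um2_per_mm2)
  if (n_ley > 0) {
    cr <- params$cell_radius[["leydig"]]
    lx <- numeric(n_ley); ly <- numeric(n_ley)
    placed <- 0; guard <- 0
    while (placed < n_ley && guard < 300 * n_ley) {
      guard <- guard + 1
      cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
      if (nrow(tub) > 0 &&
          any((tub$x - cx)^2 + (tub$y - cy)^2 < (tub$outer_r + cr)^2)) next
      if (placed > 0 &&
          any((lx[seq_len(placed)] - cx)^2 +
              (ly[seq_len(placed)] - cy)^2 < (2 * cr)^2)) next
      placed <- placed + 1
      lx[placed] <- cx; ly[placed] <- cy
    }
    if (placed < n_ley) {
      stop(sprintf("could not place all Leydig profiles (%d of %d)",
                   placed, n_ley))
    }
    cells <- rbind(cells, data.frame(x = lx, y = ly, r = cr,
                                     class = "leydig"))
  }

  structure(list(
    width = W, height = H,
    tubules = tub, cells = cells,
    achieved_tubule_fraction = achieved / A,
    params = params, seed = seed
  ), class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("<tissue_geometry> %g x %g um, %d tubules (area fraction %.3f), %d cells\n",
              x$width, x$height, nrow(x$tubules),
              x$achieved_tubule_fraction, nrow(x$cells)))
  if (nrow(x$cells)) print(table(x$cells$class))
  invisible(x)
}

#' Analytic ground truth for a synthetic field
#'
#' Exact area fractions of the three tissue compartments, the tubule
#' outer-boundary length density and the cell profile densities, computed
#' from the circle descriptions (border-crossing circles clipped exactly),
#' not from any raster.
#'
#' @param geom A [generate_geometry()] result.
#' @return Object of class `ground_truth` with components `A_A` (named
#'   fractions `epithelium`, `lumen`, `interstitium`, summing to 1), `B_A`
#'   (tubule outer boundary length per tissue area, 1/mm) and `N_A` (named
#'   profile densities per mm^2 for `leydig`, `sertoli`, `germ`).
#' @export
analytic_ground_truth <- function(geom) {
  stopifnot(inherits(geom, "tissue_geometry"))
  W <- geom$width; H <- geom$height; A <- W * H
  tub <- geom$tubules
  if (nrow(tub)) {
    outer_areas <- mapply(disk_rect_area, tub$x, tub$y, tub$outer_r,
                          0, 0, W, H)
    lumen_areas <- mapply(function(x, y, r)
      if (r > 0) disk_rect_area(x, y, r, 0, 0, W, H) else 0,
      tub$x, tub$y, tub$lumen_r)
    perim <- sum(mapply(circle_rect_arclength, tub$x, tub$y, tub$outer_r,
                        0, 0, W, H))
  } else {
    outer_areas <- lumen_areas <- 0
    perim <- 0
  }
  a_lumen <- sum(lumen_areas)
  a_epi <- sum(outer_areas) - a_lumen
  a_int <- A - sum(outer_areas)
  counts <- c(leydig = 0, sertoli = 0, germ = 0)
  if (nrow(geom$cells)) {
    tb <- table(geom$cells$class)
    counts[names(tb)] <- as.numeric(tb)
  }
  structure(list(
    A_A = c(epithelium = a_epi / A, lumen = a_lumen / A,
            interstitium = a_int / A),
    B_A = perim / A * 1000,          # um/um^2 -> 1/mm
    N_A = counts / (A / 1e6)         # profiles per mm^2
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n  A_A:",
      paste(sprintf("%s %.4f", names(x$A_A), x$A_A), collapse = ", "),
      sprintf("\n  B_A: %.3f /mm\n  N_A:", x$B_A),
      paste(sprintf("%s %.1f", names(x$N_A), x$N_A), collapse = ", "), "/mm^2\n")
  invisible(x)
}

#' Rasterise a field into an integer label image
#'
#' Pixel-centre sampling of the compartment labels. Cell classes are overlaid
#' on their host compartment. Raster area fractions converge to the analytic
#' ground truth as `pixel_size` shrinks.
#'
#' @param geom A [generate_geometry()] result.
#' @param pixel_size Pixel edge in micrometres per pixel.
#' @param max_pixels Guard against accidental huge rasters.
#' @param classes Cell classes to overlay (default all three).
#' @return Integer matrix (rows = y, cols = x) with labels 0 interstitium,
#'   1 epithelium, 2 lumen, 3 Leydig, 4 Sertoli, 5 germ; attribute
#'   `pixel_size` records the resolution.
#' @export
rasterize_labels <- function(geom, pixel_size, max_pixels = 4e7,
                             classes = c("leydig", "sertoli", "germ")) {
  stopifnot(inherits(geom, "tissue_geometry"), pixel_size > 0)
  nx <- max(1L, round(geom$width / pixel_size))
  ny <- max(1L, round(geom$height / pixel_size))
  if (as.double(nx) * ny > max_pixels) {
    stop(sprintf("raster of %d x %d pixels exceeds the pixel budget", nx, ny))
  }
  px <- (seq_len(nx) - 0.5) * pixel_size
  py <- (seq_len(ny) - 0.5) * pixel_size
  lab <- matrix(0L, nrow = ny, ncol = nx)
  paint_disk <- function(lab, cx, cy, r, value, only_when = NULL) {
    jx <- which(px >= cx - r & px <= cx + r)
    jy <- which(py >= cy - r & py <= cy + r)
    if (!length(jx) || !length(jy)) return(lab)
    dx2 <- (px[jx] - cx)^2
    dy2 <- (py[jy] - cy)^2
    inside <- outer(dy2, dx2, "+") <= r^2
    sub <- lab[jy, jx, drop = FALSE]
    sel <- inside
    if (!is.null(only_when)) sel <- inside & (sub %in% only_when)
    sub[sel] <- value
    lab[jy, jx] <- sub
    lab
  }
  tub <- geom$tubules
  if (nrow(tub)) for (i in seq_len(nrow(tub))) {
    lab <- paint_disk(lab, tub$x[i], tub$y[i], tub$outer_r[i], 1L)
    if (tub$lumen_r[i] > 0) {
      lab <- paint_disk(lab, tub$x[i], tub$y[i], tub$lumen_r[i], 2L)
    }
  }
  cl <- geom$cells
  cl <- cl[cl$class %in% classes, , drop = FALSE]
  if (nrow(cl)) {
    code <- c(leydig = 3L, sertoli = 4L, germ = 5L)
    for (i in seq_len(nrow(cl))) {
      lab <- paint_disk(lab, cl$x[i], cl$y[i], cl$r[i], code[[cl$class[i]]])
    }
  }
  attr(lab, "pixel_size") <- pixel_size
  lab
}

#' Raster area fractions of the three tissue compartments
#'
#' Helper for resolution-convergence checks: compartment area fractions
#' computed by counting pixels of a label raster (cell labels are folded back
#' into their host compartment).
#'
#' @param lab A [rasterize_labels()] raster.
#' @return Named fractions as in [analytic_ground_truth()]'s `A_A`.
#' @export
raster_area_fractions <- function(lab) {
  # cells: leydig hosts in interstitium; sertoli/germ in epithelium
  host <- c(`0` = 0L, `1` = 1L, `2` = 2L, `3` = 0L, `4` = 1L, `5` = 1L)
  h <- host[as.character(lab)]
  n <- length(h)
  c(epithelium = sum(h == 1L) / n,
    lumen = sum(h == 2L) / n,
    interstitium = sum(h == 0L) / n)
}
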