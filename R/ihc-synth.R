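# Synthesis of DAB-immunostained RGB fields with a known positive mask.
#
# DAB-positive staining is laid down inside Leydig-cell profiles until the
# positive area reaches a prescribed fraction of the interstitial area; the
# optical densities are then pushed through the inverse Beer-Lambert
# transform with fixed H/DAB stain colour vectors to produce an RGB image.

#' Ruifrok-Johnston H/DAB stain colour matrix
#'
#' Columns are the unit optical-density colour vectors of hematoxylin and
#' DAB used both for synthesis and for colour deconvolution, so the
#' quantification side can invert the synthesis exactly.
#'
#' @return 3 x 2 matrix (rows R, G, B; columns `hematoxylin`, `dab`).
#' @export
hdab_stain_matrix <- function() {
  m <- cbind(hematoxylin = c(0.650, 0.704, 0.286),
             dab = c(0.268, 0.570, 0.776))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Parameters for DAB field synthesis
#'
#' @param positive_area_fraction_of_interstitium Target DAB-positive area as
#'   a fraction of the interstitial area, in `[0, 1]`. Positive staining is
#'   realised only inside Leydig profiles.
#' @param dab_od_mean,dab_od_sd Per-pixel DAB optical density of positive
#'   pixels: Normal(mean, sd) clipped at 0.
#' @param background_od Hematoxylin optical density of all non-positive
#'   tissue pixels.
#' @param noise_sd Per-pixel Gaussian noise added on the 0-255 intensity
#'   scale.
#' @param pixel_size Micrometres per pixel.
#' @return Object of class `ihc_synth_params`.
#' @export
ihc_synth_params <- function(positive_area_fraction_of_interstitium = 0.10,
                             dab_od_mean = 0.5, dab_od_sd = 0.02,
                             background_od = 0.05, noise_sd = 2,
                             pixel_size = 1) {
  stopifnot(positive_area_fraction_of_interstitium >= 0,
            positive_area_fraction_of_interstitium <= 1,
            dab_od_mean >= 0, dab_od_sd >= 0, background_od >= 0,
            noise_sd >= 0, pixel_size > 0)
  structure(list(
    positive_area_fraction_of_interstitium =
      positive_area_fraction_of_interstitium,
    dab_od_mean = dab_od_mean, dab_od_sd = dab_od_sd,
    background_od = background_od, noise_sd = noise_sd,
    pixel_size = pixel_size
  ), class = "ihc_synth_params")
}

#' Synthesise a DAB-immunostained RGB field
#'
#' Rasterises the field, selects Leydig pixels cell by cell (random cell
#' order, the last cell filled from its centre outwards) until the positive
#' area equals the requested fraction of the interstitial area up to pixel
#' quantisation, assigns optical densities (DAB for positive pixels,
#' hematoxylin background elsewhere), converts OD to RGB through the inverse
#' Beer-Lambert transform with the [hdab_stain_matrix()] colour vectors, and
#' adds per-pixel Gaussian intensity noise. Intensities are kept as
#' unquantised doubles in `[0, 255]` so that the zero-noise round trip
#' through the quantification side is exact.
#'
#' @param geom A [generate_geometry()] field containing Leydig profiles.
#' @param p An [ihc_synth_params()] object.
#' @param seed Integer seed.
#' @return Object of class `ihc_field`: `rgb` (ny x nx x 3 array, 0-255),
#'   `mask` (true positive pixels), `roi` (interstitial pixels, Leydig
#'   included), `od_true` (per-pixel DAB OD), `labels`, `stain_matrix`,
#'   realised `positive_fraction`, and the parameters and seed used.
#' @export
synthesize_ihc_field <- function(geom, p, seed) {
  stopifnot(inherits(geom, "tissue_geometry"), inherits(p, "ihc_synth_params"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  lab <- rasterize_labels(geom, p$pixel_size, classes = "leydig")
  roi <- lab == 0L | lab == 3L          # interstitium, Leydig included
  n_roi <- sum(roi)
  n_pos <- round(p$positive_area_fraction_of_interstitium * n_roi)
  ley <- geom$cells[geom$cells$class == "leydig", , drop = FALSE]
  mask <- matrix(FALSE, nrow = nrow(lab), ncol = ncol(lab))
  if (n_pos > 0) {
    if (nrow(ley) == 0) stop("field has no Leydig profiles to stain")
    ny <- nrow(lab); nx <- ncol(lab)
    px_x <- (col(lab) - 0.5) * p$pixel_size
    px_y <- (row(lab) - 0.5) * p$pixel_size
    ley_idx <- which(lab == 3L)
    if (length(ley_idx) < n_pos) {
      stop(sprintf(
        "requested positive area (%d px) exceeds total Leydig profile area (%d px)",
        n_pos, length(ley_idx)))
    }
    # assign each Leydig pixel to its (non-overlapping) cell
    owner <- integer(length(ley_idx))
    for (i in seq_len(nrow(ley))) {
      d2 <- (px_x[ley_idx] - ley$x[i])^2 + (px_y[ley_idx] - ley$y[i])^2
      owner[d2 <= ley$r[i]^2] <- i
    }
    ord <- sample.int(nrow(ley))
    remaining <- n_pos
    for (i in ord) {
      if (remaining <= 0) break
      cell_px <- ley_idx[owner == i]
      if (!length(cell_px)) next
      if (length(cell_px) <= remaining) {
        mask[cell_px] <- TRUE
        remaining <- remaining - length(cell_px)
      } else {
        d2 <- (px_x[cell_px] - ley$x[i])^2 + (px_y[cell_px] - ley$y[i])^2
        take <- cell_px[order(d2)][seq_len(remaining)]
        mask[take] <- TRUE
        remaining <- 0
      }
    }
    if (remaining > 0) {
      stop("could not realise the requested positive area inside Leydig profiles")
    }
  }
  od_dab <- matrix(0, nrow = nrow(lab), ncol = ncol(lab))
  npx <- sum(mask)
  if (npx > 0) {
    od_dab[mask] <- pmax(stats::rnorm(npx, p$dab_od_mean, p$dab_od_sd), 0)
  }
  od_h <- matrix(p$background_od, nrow = nrow(lab), ncol = ncol(lab))
  od_h[mask] <- 0
  M <- hdab_stain_matrix()
  rgb <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3) {
    od_ch <- od_h * M[ch, 1] + od_dab * M[ch, 2]
    I <- 255 * 10^(-od_ch)
    if (p$noise_sd > 0) I <- I + stats::rnorm(length(I), 0, p$noise_sd)
    rgb[, , ch] <- matrix(pmin(pmax(I, 0), 255), nrow = nrow(lab))
  }
  structure(list(
    rgb = rgb, mask = mask, roi = roi, od_true = od_dab, labels = lab,
    stain_matrix = M,
    positive_fraction = sum(mask) / n_roi,
    params = p, seed = seed
  ), class = "ihc_field")
}

#' @export
print.ihc_field <- function(x, ...) {
  cat(sprintf("<ihc_field> %d x %d px, positive fraction of interstitium %.4f (target %.4f)\n",
              nrow(x$mask), ncol(x$mask), x$positive_fraction,
              x$params$positive_area_fraction_of_interstitium))
  invisible(x)
}

#' Write an RGB field as an 8-bit PNG
#'
#' Thin export helper (quantises to 8 bits); requires the `png` package.
#'
#' @param field An [synthesize_ihc_field()] result or a 0-255 RGB array.
#' @param path Output file.
#' @export
write_ihc_png <- function(field, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required for PNG export")
  }
  rgb <- if (inherits(field, "ihc_field")) field$rgb else field
  png::writePNG(round(rgb) / 255, path)
  invisible(path)
}
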