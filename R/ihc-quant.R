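# Quantification of DAB immunoreactivity on RGB fields: optical-density
# transform, colour deconvolution, fixed-threshold segmentation, and the two
# summary measures IRA (% immunoreactive area of the interstitial ROI) and
# IOD (mean DAB optical density over the immunoreactive area).

#' Convert an RGB image to per-channel optical density
#'
#' `OD = log10(I0 / max(I, 1))` per channel; the clamp guards zero
#' intensities.
#'
#' @param rgb Numeric array `ny x nx x 3` with intensities in `[0, 255]`.
#' @param I0 Reference (blank) intensity, default 255.
#' @return Array of the same shape with non-negative optical densities.
#' @export
rgb_to_od <- function(rgb, I0 = 255) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3, I0 > 0)
  pmax(log10(I0 / pmax(rgb, 1)), 0)
}

#' Separate the DAB channel by colour deconvolution
#'
#' Least-squares unmixing of the per-pixel OD vector against the two-column
#' stain matrix. Negative unmixed densities are clipped to zero and the
#' number of clipped pixels is recorded.
#'
#' @param od An [rgb_to_od()] array.
#' @param stain_matrix 3 x 2 OD colour matrix, columns hematoxylin and DAB
#'   (default [hdab_stain_matrix()]).
#' @return Object of class `od_image`: matrices `dab` and `hematoxylin`,
#'   `clipped` (count of clipped pixels per channel), `stain_matrix`.
#' @export
separate_dab <- function(od, stain_matrix = hdab_stain_matrix()) {
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 3,
            is.matrix(stain_matrix), nrow(stain_matrix) == 3,
            ncol(stain_matrix) == 2)
  gram <- crossprod(stain_matrix)
  if (abs(det(gram)) < 1e-10) stop("stain matrix is singular")
  pinv <- solve(gram, t(stain_matrix))    # 2 x 3 pseudo-inverse
  ny <- dim(od)[1]; nx <- dim(od)[2]
  flat <- matrix(od, nrow = ny * nx, ncol = 3)
  conc <- flat %*% t(pinv)                # n x 2: hematoxylin, dab
  clipped <- colSums(conc < 0)
  conc[conc < 0] <- 0
  structure(list(
    hematoxylin = matrix(conc[, 1], nrow = ny, ncol = nx),
    dab = matrix(conc[, 2], nrow = ny, ncol = nx),
    clipped = c(hematoxylin = clipped[1], dab = clipped[2]),
    stain_matrix = stain_matrix
  ), class = "od_image")
}

#' Fixed DAB detection threshold from calibration set points
#'
#' The study-wide threshold is established once, as the midpoint between the
#' background DAB optical density and the weakest expected positive DAB
#' density, and then applied uniformly to every field and group.
#'
#' @param background_od DAB-channel OD of background tissue (0 for a pure
#'   hematoxylin background).
#' @param weakest_positive_od Lowest positive DAB OD set point across the
#'   study (the default is the weakest group set point of the packaged
#'   cohort configuration).
#' @return Threshold in OD units.
#' @export
calibrate_dab_threshold <- function(background_od = 0,
                                    weakest_positive_od = 0.2452) {
  stopifnot(background_od >= 0, weakest_positive_od > background_od)
  (background_od + weakest_positive_od) / 2
}

#' Quantify one DAB field
#'
#' Pixels of the DAB channel at or above the fixed threshold, within the
#' interstitial region of interest, are immunoreactive. `IRA` is their
#' percentage of the ROI area; `IOD` is the mean DAB optical density over
#' the immunoreactive pixels (0, and flagged, when none are positive).
#'
#' @param dab An [separate_dab()] result or a DAB OD matrix.
#' @param roi Logical matrix marking the interstitial ROI (ground-truth
#'   labels in simulation; a user-supplied mask for real images).
#' @param threshold Fixed DAB OD threshold, single study-wide value.
#' @return Object of class `ihc_result`: `ira` (percent), `iod` (OD units),
#'   `n_positive`, `n_roi`, `threshold`, `no_positive` flag.
#' @export
quantify_field <- function(dab, roi, threshold = calibrate_dab_threshold()) {
  if (inherits(dab, "od_image")) dab <- dab$dab
  stopifnot(is.matrix(dab), is.logical(roi), all(dim(dab) == dim(roi)),
            threshold > 0)
  n_roi <- sum(roi)
  if (n_roi == 0) stop("empty ROI")
  pos <- dab >= threshold & roi
  n_pos <- sum(pos)
  structure(list(
    ira = 100 * n_pos / n_roi,
    iod = if (n_pos > 0) mean(dab[pos]) else 0,
    n_positive = n_pos, n_roi = n_roi,
    threshold = threshold, no_positive = n_pos == 0
  ), class = "ihc_result")
}

#' @export
print.ihc_result <- function(x, ...) {
  cat(sprintf("<ihc_result> IRA = %.2f%%, IOD = %.4f (%d of %d ROI px >= OD %.3f)\n",
              x$ira, x$iod, x$n_positive, x$n_roi, x$threshold))
  invisible(x)
}

#' Aggregate field results to one animal
#'
#' Arithmetic mean of the per-field IRA and IOD values (the per-animal
#' quantities entering the statistical analysis).
#'
#' @param fields List of [quantify_field()] results (typically 5).
#' @return Object of class `ihc_result` with the per-animal means and
#'   `n_fields`.
#' @export
aggregate_animal <- function(fields) {
  stopifnot(length(fields) >= 1,
            all(vapply(fields, inherits, TRUE, "ihc_result")))
  structure(list(
    ira = mean(vapply(fields, function(f) f$ira, 0)),
    iod = mean(vapply(fields, function(f) f$iod, 0)),
    n_fields = length(fields),
    threshold = fields[[1]]$threshold
  ), class = "ihc_result")
}

#' Run the full quantification chain on one synthetic field
#'
#' Convenience wrapper: RGB to OD, colour deconvolution, thresholded
#' quantification against the field's interstitial ROI.
#'
#' @param field A [synthesize_ihc_field()] result.
#' @param threshold Fixed DAB OD threshold.
#' @return A [quantify_field()] result.
#' @export
quantify_ihc_field <- function(field,
                               threshold = calibrate_dab_threshold()) {
  stopifnot(inherits(field, "ihc_field"))
  od <- rgb_to_od(field$rgb)
  sep <- separate_dab(od, field$stain_matrix)
  quantify_field(sep, field$roi, threshold)
}
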