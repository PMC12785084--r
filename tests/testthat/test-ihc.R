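# DAB synthesis and quantification: OD transform, colour deconvolution
# round trip, thresholding, aggregation, and the monotonicity / scale
# invariance properties.

test_that("optical density transform follows the Beer-Lambert log ratio", {
  img <- array(255, dim = c(2, 2, 3))
  expect_equal(rgb_to_od(img), array(0, dim = c(2, 2, 3)))
  img[1, 1, ] <- 25.5
  expect_equal(rgb_to_od(img)[1, 1, 1], 1)
  img[2, 2, ] <- 0                       # guarded division by zero
  expect_equal(rgb_to_od(img)[2, 2, 1], log10(255))
})

test_that("colour deconvolution inverts the synthesis exactly at zero noise", {
  g <- fixture_geom()
  p0 <- ihc_synth_params(0.10, dab_od_mean = 0.6, dab_od_sd = 0,
                         noise_sd = 0, pixel_size = 2)
  f <- synthesize_ihc_field(g, p0, 1)
  sep <- separate_dab(rgb_to_od(f$rgb), f$stain_matrix)
  expect_lt(max(abs(sep$dab[f$mask] - f$od_true[f$mask])), 1e-6)
  # pure-DAB pixels carry (numerically) no hematoxylin
  expect_lt(max(abs(sep$hematoxylin[f$mask])), 1e-6)
  # mask-restricted mean OD equals the set point exactly
  expect_equal(mean(sep$dab[f$mask]), 0.6, tolerance = 1e-9)
  # all-white image unmixes to zero everywhere
  white <- separate_dab(rgb_to_od(array(255, dim = c(4, 4, 3))))
  expect_true(all(white$dab == 0) && all(white$hematoxylin == 0))
  expect_error(separate_dab(rgb_to_od(array(255, dim = c(2, 2, 3))),
                            cbind(c(1, 0, 0), c(1, 0, 0))), "singular")
})

test_that("positive area matches the requested interstitial fraction", {
  g <- fixture_geom()
  p <- ihc_synth_params(0.10, pixel_size = 1)
  f <- synthesize_ihc_field(g, p, 2)
  expect_equal(sum(f$mask) / sum(f$roi), 0.10, tolerance = 1e-4)
  # zero fraction: empty mask, zero IRA downstream
  f0 <- synthesize_ihc_field(g, ihc_synth_params(0, pixel_size = 2), 3)
  expect_equal(sum(f0$mask), 0)
  expect_equal(quantify_ihc_field(f0)$ira, 0)
  # impossible request: more than the Leydig compartment can hold
  expect_error(synthesize_ihc_field(g, ihc_synth_params(0.9, pixel_size = 2), 4),
               "exceeds total Leydig")
})

test_that("field quantification computes IRA and IOD from the thresholded ROI", {
  dab <- matrix(0, 10, 10)
  roi <- matrix(TRUE, 10, 10)
  dab[1:5, ] <- 0.5                      # half the ROI positive at OD 0.5
  q <- quantify_field(dab, roi, threshold = 0.2)
  expect_equal(q$ira, 50)
  expect_equal(q$iod, 0.5)
  # nothing positive: IRA 0, IOD 0, flagged
  q0 <- quantify_field(matrix(0.01, 5, 5), matrix(TRUE, 5, 5), 0.2)
  expect_equal(q0$ira, 0)
  expect_equal(q0$iod, 0)
  expect_true(q0$no_positive)
  expect_error(quantify_field(dab, matrix(FALSE, 10, 10), 0.2), "empty ROI")
})

test_that("per-animal aggregation is the arithmetic field mean", {
  mk <- function(ira) structure(list(ira = ira, iod = ira / 100,
                                     threshold = 0.12),
                                class = "ihc_result")
  agg <- aggregate_animal(lapply(c(10, 20, 30, 40, 50), mk))
  expect_equal(agg$ira, 30)
  expect_equal(agg$iod, 0.30)
  one <- aggregate_animal(list(mk(12), mk(12)))
  expect_equal(one$ira, 12)
})

test_that("raising the threshold never raises IRA nor lowers IOD", {
  g <- fixture_geom()
  f <- synthesize_ihc_field(g, ihc_synth_params(0.12, dab_od_mean = 0.5,
                                                dab_od_sd = 0.05,
                                                pixel_size = 1), 5)
  sep <- separate_dab(rgb_to_od(f$rgb), f$stain_matrix)
  ths <- c(0.1, 0.2, 0.3, 0.4)
  res <- lapply(ths, function(th) quantify_field(sep, f$roi, th))
  ira <- vapply(res, function(r) r$ira, 0)
  iod <- vapply(res, function(r) r$iod, 0)
  expect_true(all(diff(ira) <= 0))
  nonempty <- !vapply(res, function(r) r$no_positive, TRUE)
  expect_true(all(diff(iod[nonempty]) >= 0))
})

test_that("IRA is invariant under doubled image resolution", {
  g <- fixture_geom()
  q1 <- quantify_ihc_field(
    synthesize_ihc_field(g, ihc_synth_params(0.10, dab_od_mean = 0.6,
                                             dab_od_sd = 0, noise_sd = 0,
                                             pixel_size = 2), 6))
  q2 <- quantify_ihc_field(
    synthesize_ihc_field(g, ihc_synth_params(0.10, dab_od_mean = 0.6,
                                             dab_od_sd = 0, noise_sd = 0,
                                             pixel_size = 1), 6))
  expect_lt(abs(q1$ira - q2$ira), 0.5)
})

test_that("the calibrated threshold is the background/weakest-positive midpoint", {
  expect_equal(calibrate_dab_threshold(0, 0.2452), 0.1226)
  expect_equal(calibrate_dab_threshold(0.1, 0.5), 0.3)
  expect_error(calibrate_dab_threshold(0.5, 0.2))
})
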