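# Grid arithmetic, probe counting rules, and estimator behaviour.

test_that("M36 grid arithmetic follows the grid definition", {
  g <- build_grid(25, seed = 1)
  expect_equal(g$n_points, 36L)
  expect_equal(g$total_test_line, 450)     # 18 d
  expect_equal(g$test_area, 22725)         # 36.36 d^2
  expect_equal(g$area_per_point, 1.01 * 25^2)
  g1 <- build_grid(1, seed = 2)
  expect_equal(g1$area_per_point, 1.01)
  # same seed, same placement
  expect_identical(build_grid(25, 3)$offset, build_grid(25, 3)$offset)
  expect_error(build_grid(25, 1, frame_side = 200),
               "must not exceed the test area")
})

test_that("an all-lumen field puts all 36 points in the lumen", {
  tub <- data.frame(x = 300, y = 300, outer_r = 5000, lumen_r = 4000)
  g <- manual_geometry(600, 600, tubules = tub)
  rec <- count_field(g, build_grid(100, 1))
  expect_equal(unname(rec$P[["lumen"]]), 36)
  expect_equal(rec$SP, 36)
})

test_that("a chord-crossing segment yields two intersections", {
  # one tubule centred on a known segment path; count by direct probe
  tub <- data.frame(x = 300, y = 300, outer_r = 20, lumen_r = 10)
  g <- manual_geometry(600, 600, tubules = tub)
  # grids until one segment crosses: the total I over many grids must be even
  # apart from tangencies; assert the direct primitive instead
  expect_equal(segment_circle_intersections(250, 300, 350, 300,
                                            300, 300, 20), 2L)
  # and a field with no tubules gives I = 0, S_V = 0
  g0 <- manual_geometry(600, 600)
  rec0 <- count_field(g0, build_grid(100, 1))
  expect_equal(rec0$I, 0L)
  expect_equal(estimate_sv(list(rec0))$sv, 0)
})

test_that("the counting-frame rule accepts interior and rejects forbidden-edge profiles", {
  # frame from a grid with known placement: use frame_u = c(0,0) by
  # constructing the grid then overriding deterministically
  gr <- build_grid(100, 1, frame_side = 500)
  gr$frame_u <- c(0, 0)    # frame [0,500] x [0,500]
  cells <- data.frame(
    x = c(250, 499, 250),
    y = c(250, 250, 1),
    r = c(10, 10, 10),
    class = c("leydig", "leydig", "leydig"))
  # cell 1 wholly inside; cell 2 touches the right (forbidden) edge;
  # cell 3 touches the bottom (forbidden) edge
  g <- manual_geometry(600, 600, cells = cells)
  rec <- count_field(g, gr)
  expect_equal(unname(rec$Q[["leydig"]]), 1)
})

test_that("toroidal frame placement accepts every profile with probability a_frame / A", {
  # quasi-exhaustive average over frame positions approximates the exact
  # inclusion probability for each profile irrespective of its position
  cells <- data.frame(x = c(30, 295, 150), y = c(290, 15, 150),
                      r = c(8, 8, 8),
                      class = c("leydig", "sertoli", "germ"))
  g <- manual_geometry(300, 300, cells = cells)
  gr <- build_grid(50, 1, frame_side = 200)
  set.seed(606)
  n_pos <- 4000
  tot <- 0
  for (k in seq_len(n_pos)) {
    gr$frame_u <- stats::runif(2)
    tot <- tot + sum(count_field(g, gr)$Q)
  }
  p_hat <- tot / (n_pos * nrow(cells))
  expect_equal(p_hat, 200^2 / 300^2, tolerance = 0.04)
})

test_that("volume density pools point counts and reports ratio CEs", {
  r1 <- make_count_record(c(epithelium = 13, lumen = 5, interstitium = 18))
  vv <- estimate_vv(list(r1))
  expect_equal(vv$vv_pct[vv$compartment == "epithelium"], 100 * 13 / 36,
               tolerance = 1e-9)
  expect_equal(sum(vv$vv[1:3]), 1)
  # identical fields: CE = 0
  vv2 <- estimate_vv(list(r1, r1, r1))
  expect_true(all(vv2$ce == 0))
  expect_error(estimate_vv(list(make_count_record(
    c(epithelium = 0, lumen = 0, interstitium = 0)))), "no test points")
})

test_that("surface density follows 2 I / L and the (pi/4) identity holds on tissue", {
  rec <- make_count_record(c(epithelium = 12, lumen = 4, interstitium = 20),
                           I = 10L, L = 450)
  sv <- estimate_sv(list(rec))
  expect_equal(sv$sv, 2 * 10 / 450 * 1000, tolerance = 1e-9)  # 44.4 / mm
  # identity against the analytic oracle on a fixed geometry, averaged over
  # grid randomisation
  g <- fixture_geom(); gt <- fixture_truth()
  recs <- lapply(1:60, function(s) count_field(g, build_grid(100, s)))
  sv2 <- estimate_sv(recs)
  expect_equal(pi / 4 * sv2$sv, gt$B_A, tolerance = 0.05)
})

test_that("numerical density divides accepted counts by sampled frame area", {
  rec <- make_count_record(c(epithelium = 12, lumen = 4, interstitium = 20),
                           Q = c(leydig = 3L, sertoli = 0L, germ = 0L),
                           a_frame = 1e4)   # 0.01 mm^2
  qa <- estimate_qa(list(rec))
  expect_equal(qa$qa[qa$class == "leydig"], 300)
  expect_equal(qa$qa[qa$class == "germ"], 0)
})

test_that("absolute volumes multiply and propagate error in quadrature", {
  av <- absolute_volume(0.30, 2.0, ce_vv = 0.03, ce_ref = 0.04)
  expect_equal(av$v_abs, 0.60)
  expect_equal(av$ce, 0.05)
  expect_equal(absolute_volume(0, 2.0)$v_abs, 0)
  expect_error(absolute_volume(1.2, 1))
})

test_that("precision decomposition subtracts noise in quadrature", {
  pr <- precision_decomposition(c(10, 10, 10), c(0, 0, 0))
  expect_equal(pr$ocv_group, 0)
  expect_equal(pr$oce_individual, 0)
  expect_equal(pr$cv_biological, 0)
  # 3-4-5: OCV 10%, OCE 6% -> biological 8%
  x <- c(90, 100, 110)                    # sd 10, mean 100: OCV exactly 10%
  pr2 <- precision_decomposition(x, rep(0.06, 3))
  expect_equal(pr2$ocv_group, 10, tolerance = 1e-9)
  expect_equal(pr2$oce_individual, 6)
  expect_equal(pr2$cv_biological, 8, tolerance = 1e-9)
  expect_error(precision_decomposition(5, 0.1), "at least 2")
})

test_that("estimator CE shrinks roughly as 1/sqrt(n_fields)", {
  p <- fixture_small_params()
  recs <- lapply(1:40, function(s) {
    count_field(generate_geometry(p, s), build_grid(50, s + 1000))
  })
  ce10 <- estimate_vv(recs[1:10])
  ce40 <- estimate_vv(recs)
  e10 <- ce10$ce[ce10$compartment == "epithelium"]
  e40 <- ce40$ce[ce40$compartment == "epithelium"]
  expect_gt(e10 / e40, 1.2)
  expect_lt(e10 / e40, 3.5)
})
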