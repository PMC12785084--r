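# Sampling chain: orientator angle laws, Cavalieri estimator and its error
# coefficient, SURS field plans, shrinkage corrections.

test_that("orientator theta class boundaries follow the cosine-weighted law", {
  expect_equal(orientator_theta_boundary(0), 0)
  expect_equal(orientator_theta_boundary(10), 90)
  expect_equal(orientator_theta_boundary(5), acos(0.5) * 180 / pi)
  a <- draw_orientator_angles(3)
  expect_true(a$phi_class %in% 0:9)
  expect_true(a$theta_class %in% 0:9)
  expect_equal(a$phi, 36 * a$phi_class + 18)
  # theta lies inside its class interval
  expect_gte(a$theta, orientator_theta_boundary(a$theta_class))
  expect_lte(a$theta, orientator_theta_boundary(a$theta_class + 1))
})

test_that("cos(theta) is uniform on [0,1] over many seeded draws", {
  n <- 1e5
  ct <- vapply(seq_len(n), function(s) {
    cos(draw_orientator_angles(s)$theta * pi / 180)
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ct, "punif"))
  expect_lt(unname(ks$statistic), 0.01)
  # phi classes uniform as well
  pc <- vapply(seq_len(2000), function(s) draw_orientator_angles(s)$phi_class, 0L)
  expect_gt(stats::chisq.test(table(factor(pc, levels = 0:9)))$p.value, 1e-4)
})

test_that("Cavalieri volume and CE behave on constant and short series", {
  cv <- cavalieri_volume(c(1, 1, 1, 1), t = 1)
  expect_equal(cv$volume, 4)
  expect_equal(cv$ce, 0)                  # constant series: zero error
  expect_error(cavalieri_volume(c(1, 1), 1), "at least 3")
  # non-constant series has positive CE
  expect_gt(cavalieri_volume(c(1, 3, 2, 5), 1)$ce, 0)
})

test_that("Cavalieri estimator is unbiased on sphere and ellipsoid phantoms", {
  # sphere r = 5 mm, t = 1 mm, averaged over 200 uniform random starts
  set.seed(11)
  vols <- replicate(200, {
    cavalieri_volume(ellipsoid_slab_areas(c(5, 5, 5), 1,
                                          stats::runif(1, 0, 1)), 1)$volume
  })
  expect_equal(mean(vols), 4 / 3 * pi * 125, tolerance = 0.01)
  # ellipsoid (2, 3, 4) mm
  vols2 <- replicate(200, {
    cavalieri_volume(ellipsoid_slab_areas(c(2, 3, 4), 0.8,
                                          stats::runif(1, 0, 0.8)), 0.8)$volume
  })
  expect_equal(mean(vols2), 4 / 3 * pi * 24, tolerance = 0.01)
})

test_that("SURS plans are deterministic and cover the section uniformly", {
  p1 <- plan_surs_fields(c(1000, 800), 6, seed = 5)
  p2 <- plan_surs_fields(c(1000, 800), 6, seed = 5)
  expect_identical(p1$positions, p2$positions)
  expect_equal(nrow(p1$positions), 6)
  expect_true(all(p1$positions$x >= 0 & p1$positions$x <= 1000))
  expect_true(all(p1$positions$y >= 0 & p1$positions$y <= 800))
  # single field: uniformly random
  p3 <- plan_surs_fields(c(100, 100), 1, seed = 9)
  expect_equal(nrow(p3$positions), 1)
  # coverage over many seeds: chi-square on a 5 x 5 binning
  xs <- ys <- numeric(0)
  for (s in 1:2000) {
    pp <- plan_surs_fields(c(500, 500), 5, seed = s)$positions
    xs <- c(xs, pp$x); ys <- c(ys, pp$y)
  }
  counts <- table(cut(xs, seq(0, 500, length.out = 6)),
                  cut(ys, seq(0, 500, length.out = 6)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("shrinkage factors obey the power laws and thickness calibration", {
  f <- compute_shrinkage(c(20, 20, 20), c(18, 18, 18), 50, 10)
  expect_equal(f$f_L, 0.9)
  expect_equal(f$f_A, 0.81)
  expect_equal(f$f_V, 0.729)
  expect_equal(f$t_real, 5)               # 50 um advance over 10 sections
  # identity when nothing shrank
  f1 <- compute_shrinkage(c(10, 12), c(10, 12), 50, 10)
  expect_equal(f1$f_L, 1)
  expect_equal(correct_reference_volume(2.5, f1), 2.5,
               ignore_attr = TRUE)
  expect_equal(correct_reference_volume(2.5, f1, "processed"), 2.5,
               ignore_attr = TRUE)
  # trocar punch convenience wrapper
  fp <- punch_shrinkage(6, 5.4, 50, 10)
  expect_equal(fp$f_L, 0.9)
  expect_error(compute_shrinkage(c(10, 10), c(9, 9, 9), 50, 10),
               "same length")
})

test_that("processed-mode reference volume inverts the cubic shrinkage", {
  f <- compute_shrinkage(c(20, 20, 20), c(18, 18, 18), 50, 10)
  expect_equal(correct_reference_volume(0.729, f, "processed"), 1.0,
               ignore_attr = TRUE)
  # uniform-shrinkage mode leaves the fresh volume untouched
  expect_equal(correct_reference_volume(1.0, f), 1.0, ignore_attr = TRUE)
})
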