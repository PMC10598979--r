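test_that("segment_cost matches ordinary least squares", {
  # exact line P = 10 V + 5
  v <- seq(0, 0.4, length.out = 20)
  sc <- segment_cost(v, 10 * v + 5)
  expect_equal(sc$slope, 10, tolerance = 1e-12)
  expect_equal(sc$intercept, 5, tolerance = 1e-12)
  expect_lt(sc$sse, 1e-24)

  # two points always interpolate exactly
  sc2 <- segment_cost(c(0.1, 0.3), c(8, 11))
  expect_lt(sc2$sse, 1e-24)

  # noisy points agree with an independent normal-equation oracle (lm)
  set.seed(7)
  for (i in 1:10) {
    v <- sort(runif(20, 0, 0.5))
    p <- 12 * v + 6 + rnorm(20, 0, 0.4)
    fit <- lm(p ~ v)
    sc <- segment_cost(v, p)
    expect_equal(sc$slope, unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(sc$intercept, unname(coef(fit)[1]), tolerance = 1e-9)
    expect_equal(sc$sse, sum(resid(fit)^2), tolerance = 1e-9)
  }

  # vertical segment: degenerate flag, SSE against the mean pressure
  scd <- segment_cost(rep(0.2, 6), c(5, 6, 7, 8, 9, 10))
  expect_true(scd$degenerate)
  expect_true(is.na(scd$slope))
  expect_equal(scd$sse, sum((c(5:10) - 7.5)^2))
})

test_that("fit_piecewise recovers exact polylines and reduces to OLS at r = 1", {
  # 2-segment polyline, slopes 8 then 25, break at V = 0.25
  verts <- cbind(c(0, 0.25, 0.5), c(5, 5 + 8 * 0.25, 5 + 8 * 0.25 + 25 * 0.25))
  half <- make_polyline_half(verts, n = 80)
  fit <- fit_piecewise(half, 2)
  grid_step <- diff(half$volume[1:2])
  expect_lt(abs(fit$breakpoints[1] - 0.25), grid_step + 1e-12)
  expect_lt(fit$rsse, 1e-12)
  expect_equal(fit$slopes, c(8, 25), tolerance = 1e-9)

  # r = 1 equals segment_cost of the whole half-cycle
  set.seed(3)
  v <- seq(0, 0.4, length.out = 40)
  p <- 10 * v + rnorm(40, 0, 0.3)
  h <- list(volume = v, pressure = p, phase = "inspiration")
  f1 <- fit_piecewise(h, 1)
  sc <- segment_cost(v, p)
  expect_identical(f1$rsse, sc$sse)
  expect_identical(f1$slopes, sc$slope)

  expect_error(fit_piecewise(list(volume = v[1:8], pressure = p[1:8]), 2),
               "unfittable")
})

test_that("fit_piecewise equals exhaustive enumeration on small problems", {
  set.seed(11)
  for (i in 1:6) {
    n <- sample(22:30, 1)
    v <- seq(0, 0.5, length.out = n)
    p <- 8 + 15 * v + rnorm(n, 0, 0.5)
    h <- list(volume = v, pressure = p, phase = "inspiration")
    for (r in 2:3) {
      fit <- fit_piecewise(h, r)
      oracle <- brute_force_fit(v, p, r)
      expect_identical(fit$rsse, oracle$rsse)
      expect_identical(fit$breakpoint_index, oracle$bks)
    }
  }
})

test_that("f_ratio follows its definition and propagates calibration errors", {
  h <- make_polyline_half(cbind(c(0, 0.2, 0.4), c(5, 9, 11)), n = 40)
  f2 <- fit_piecewise(h, 2)
  f3 <- fit_piecewise(h, 3)
  # identical RSSE gives F = 0 (clamped)
  same <- f3; same$r <- 3L; same$rsse <- f2$rsse
  expect_equal(f_ratio(f2, same, fixed_calib(0.5)), 0)
  # arithmetic from the definition: (5 - 2) / 0.5 = 6
  a <- f2; a$rsse <- 5
  b <- f3; b$rsse <- 2
  expect_equal(f_ratio(a, b, fixed_calib(0.5)), 6)
  expect_error(f_ratio(a, b, fixed_calib(0)), "calibration error")
  expect_error(f_ratio(f2, f2, fixed_calib(0.5)), "r \\+ 1")

  # noise-free 3-segment polyline: F(3|2) huge (RSSE_3 ~ 0, RSSE_2 > 0)
  verts <- cbind(c(0, 0.15, 0.3, 0.45), c(5, 8, 7, 12))
  h3 <- make_polyline_half(verts, n = 60)
  g2 <- fit_piecewise(h3, 2)
  g3 <- fit_piecewise(h3, 3)
  expect_lt(g3$rsse, 1e-12)
  expect_gt(f_ratio(g2, g3, fixed_calib(1e-6)), 1e4)
})

test_that("select_model accepts the true segment count", {
  calib <- fixed_calib(1e-6)
  # noise-free 2-segment polyline: null accepted immediately
  h2 <- make_polyline_half(cbind(c(0, 0.25, 0.5), c(5, 8, 14)), n = 80)
  expect_equal(select_model(h2, calib)$r, 2L)

  # noise-free 4-segment flow-asynchrony archetype: cascade reaches r = 4
  verts <- cbind(c(0, 0.05, 0.14, 0.3, 0.45),
                 c(7.7, 8.3, 4.9, 11.9, 14.9))
  h4 <- make_polyline_half(verts, n = 130)
  expect_equal(select_model(h4, calib)$r, 4L)
})

test_that("calibrate_variance pools two-segment residual variances", {
  # noise-free polylines: sigma2 collapses to the floor with a warning
  halves <- replicate(5, make_polyline_half(
    cbind(c(0, 0.25, 0.5), c(5, 8, 14)), n = 60), simplify = FALSE)
  expect_warning(cal <- calibrate_variance(halves), "floor")
  expect_equal(cal$sigma2, 1e-6)
  expect_true(cal$floored)

  # single half-cycle: sigma2 is exactly RSSE / (N - 4)
  set.seed(21)
  h <- make_polyline_half(cbind(c(0, 0.25, 0.5), c(5, 8, 14)),
                          n = 60, noise_sd = 0.3)
  f2 <- fit_piecewise(h, 2)
  cal1 <- calibrate_variance(list(h))
  expect_equal(cal1$sigma2, f2$rsse / (60 - 4), tolerance = 1e-12)
  expect_equal(cal1$n_breaths_used, 1L)

  # 200 noisy halves at sd 0.5: sigma2 = 0.25 within 10%
  set.seed(22)
  many <- replicate(200, make_polyline_half(
    cbind(c(0, 0.25, 0.5), c(5, 10, 20)), n = 80, noise_sd = 0.5),
    simplify = FALSE)
  cal200 <- calibrate_variance(many)
  expect_equal(cal200$sigma2, 0.25, tolerance = 0.1)
  # the robust median variant agrees on clean data
  calm <- calibrate_variance(many, method = "median")
  expect_equal(calm$sigma2, 0.25, tolerance = 0.1)

  expect_error(calibrate_variance(list()), "calibration error")
})

test_that("model recovery improves with segment-slope contrast", {
  # true 3-segment polylines; recovery rate of r = 3 rises with the
  # contrast of the middle slope (non-strict, seeded)
  rates <- vapply(c(0.5, 3, 10), function(contrast) {
    set.seed(33)
    hit <- 0
    for (i in 1:25) {
      verts <- cbind(c(0, 0.18, 0.32, 0.5),
                     c(5, 5 + 10 * 0.18,
                       5 + 10 * 0.18 - contrast * 0.14,
                       5 + 10 * 0.18 - contrast * 0.14 + 10 * 0.18))
      h <- make_polyline_half(verts, n = 90, noise_sd = 0.2)
      fit <- select_model(h, fixed_calib(0.04), r_max = 3)
      if (fit$r == 3L) hit <- hit + 1
    }
    hit / 25
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})
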