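test_that("waveform_record validates the uniform-grid invariants", {
  t <- seq(0, 9.99, by = 0.01)
  rec <- waveform_record(t, rnorm(1000, 10), rnorm(1000, 0, 0.1))
  expect_s3_class(rec, "waveform_record")
  expect_equal(rec$sample_rate, 100, tolerance = 1e-9)

  t_bad <- t; t_bad[500] <- t_bad[499]          # repeated time stamp
  expect_error(waveform_record(t_bad, rnorm(1000), rnorm(1000)),
               "strictly increasing")
  t_jit <- t; t_jit[500] <- t_jit[500] + 0.003  # non-uniform spacing
  expect_error(waveform_record(t_jit, rnorm(1000), rnorm(1000)),
               "non-uniform")
  expect_error(waveform_record(t, rnorm(999), rnorm(1000)),
               "identical length")
})

test_that("read_waveform parses the CSV dialect and flags format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(5)
  rec <- waveform_record(seq(0, 0.99, by = 0.01), rnorm(100, 12, 1),
                         rnorm(100, 0.2, 0.05))
  write_waveform(rec, path)
  back <- read_waveform(path)
  # round trip is bit-identical on values
  expect_identical(back$pressure, rec$pressure)
  expect_identical(back$flow, rec$flow)
  expect_identical(back$time, rec$time)

  # missing column is a format error
  df <- utils::read.csv(path, check.names = FALSE)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, c("time_s", "paw_cmH2O")], path2, row.names = FALSE)
  expect_error(read_waveform(path2), "format error")

  # a volume column overrides integration downstream
  rec_v <- waveform_record(rec$time, rec$pressure, rec$flow,
                           volume = seq(0, 0.495, by = 0.005))
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_waveform(rec_v, path3)
  expect_identical(read_waveform(path3)$volume, rec_v$volume)
})

test_that("integrate_volume is a trapezoidal cumulative integral", {
  # constant flow: rectangle rule is exact
  v <- integrate_volume(rep(0.5, 101), 0.01)
  expect_equal(v[1], 0)
  expect_equal(v[101], 0.5, tolerance = 1e-12)
  # all-zero flow
  expect_equal(integrate_volume(rep(0, 50), 0.01), rep(0, 50))
  # triangular ramp 0 -> 1 L/s over 1 s: integral 0.5 L (closed form)
  ramp <- seq(0, 1, length.out = 101)
  expect_equal(integrate_volume(ramp, 0.01)[101], 0.5, tolerance = 1e-12)
  expect_error(integrate_volume(numeric(0), 0.01), "empty")

  # linearity property over random flows
  set.seed(1)
  for (i in 1:20) {
    f <- rnorm(80); g <- rnorm(80); a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(integrate_volume(a * f + b * g, 0.01),
                 a * integrate_volume(f, 0.01) + b * integrate_volume(g, 0.01),
                 tolerance = 1e-12)
  }
})

test_that("segment_breaths recovers simulated breaths and handles edge cases", {
  cfg <- sim_config(noise_sd_pressure = 0, noise_sd_flow = 0)
  sim <- simulate_sequence(cfg, mix = c(fa = 0), n_breaths = 5, seed = 3)
  breaths <- segment_breaths(sim$record)
  expect_length(breaths, 5)

  # 60 s at 15 breaths/min: 15 breaths of ~400 samples each at 100 Hz
  sim15 <- simulate_sequence(cfg, mix = c(fa = 0), n_breaths = 15, seed = 3)
  b15 <- segment_breaths(sim15$record)
  expect_length(b15, 15)
  expect_true(all(abs(vapply(b15, function(b) length(b$time), numeric(1)) - 400) <= 2))

  # constant zero flow: no breath, empty list (not an error)
  flat <- waveform_record(seq(0, 9.99, 0.01), rep(5, 1000), rep(0, 1000))
  expect_identical(segment_breaths(flat), list())

  # per-breath sample ranges are disjoint, ordered subsets of the record
  idx <- unlist(lapply(b15, function(b) b$start_index:b$end_index))
  expect_false(anyDuplicated(idx) > 0)
  expect_true(all(diff(idx) > 0))
  expect_true(all(idx >= 1 & idx <= length(sim15$record$time)))

  # breath invariants
  for (b in b15) {
    expect_identical(b$volume[1], 0)
    expect_equal(b$v_t, max(b$volume))
    expect_gt(b$peak_volume_index, 1)
    expect_lt(b$peak_volume_index, length(b$volume))
    expect_gte(b$peep, 0)
  }
})

test_that("split_half_cycles divides the loop at peak volume", {
  # symmetric triangular volume: halves of 201 samples each share the peak
  vol <- c(seq(0, 1, length.out = 201), seq(1, 0, length.out = 201)[-1])
  b <- breath_cycle(1L, seq_along(vol) * 0.01, rep(10, 401), rep(0, 401), vol)
  h <- split_half_cycles(b)
  expect_equal(h$inspiration$n_points, 201)
  expect_equal(h$expiration$n_points, 201)
  expect_identical(h$inspiration$volume[201], h$expiration$volume[1])

  # monotone-increasing volume: expiration collapses to one point, unfittable
  vol_up <- seq(0, 1, length.out = 100)
  b_up <- breath_cycle(1L, seq_along(vol_up) * 0.01, rep(10, 100),
                       rep(0.1, 100), vol_up)
  h_up <- split_half_cycles(b_up)
  expect_false(h_up$expiration$fittable)
  expect_true(h_up$inspiration$fittable)

  # simulated VC breath at I:E = 1:2: inspiratory half ~ 1/3 of samples
  cfg <- sim_config(noise_sd_pressure = 0, noise_sd_flow = 0)
  br <- simulate_breath(cfg, NULL)
  bc <- breath_cycle(1L, br$time, br$pressure, br$flow,
                     integrate_volume(br$flow, 0.01))
  hh <- split_half_cycles(bc)
  frac <- hh$inspiration$n_points / br$n
  expect_equal(frac, 1 / 3, tolerance = 0.02)

  # inspiration end and expiration start both sit at V_T
  expect_equal(hh$inspiration$volume[hh$inspiration$n_points], bc$v_t)
  expect_equal(hh$expiration$volume[1], bc$v_t)
})
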