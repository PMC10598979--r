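# Fixture builders and independent oracles used across the suite.

# sample a PV half-cycle from a polyline given by vertex matrix (v, p);
# points evenly spaced in volume, optional Gaussian pressure noise
make_polyline_half <- function(vertices, n = 60, noise_sd = 0,
                               phase = "inspiration") {
  v <- seq(vertices[1, 1], vertices[nrow(vertices), 1], length.out = n)
  p <- approx(vertices[, 1], vertices[, 2], xout = v)$y
  if (noise_sd > 0) p <- p + rnorm(n, 0, noise_sd)
  structure(list(phase = phase, volume = v, pressure = p, n_points = n,
                 fittable = TRUE, breath_index = 1L),
            class = "half_cycle")
}

# independent exhaustive-enumeration oracle for the breakpoint search:
# tries every admissible boundary combination on the full interior grid,
# scoring each with segment_cost() sums (left to right). Ties within 1e-12
# relative resolve to the lexicographically earliest combination.
brute_force_fit <- function(v, p, r, min_pts = 5L) {
  n <- length(v)
  seg_sse <- function(a, b) segment_cost(v[a:b], p[a:b])$sse
  if (r == 1L) return(list(rsse = seg_sse(1L, n), bks = integer(0)))
  cand <- min_pts:(n - min_pts)
  combos <- utils::combn(cand, r - 1L, simplify = FALSE)
  ok <- vapply(combos, function(b) all(diff(c(0L, b, n)) >= min_pts),
               logical(1))
  combos <- combos[ok]
  totals <- vapply(combos, function(b) {
    bounds <- c(0L, b, n)
    sum(vapply(seq_len(r), function(s)
      seg_sse(bounds[s] + 1L, bounds[s + 1L]), numeric(1)))
  }, numeric(1))
  best <- min(totals)
  hit <- which(totals <= best + 1e-12 * max(1, abs(best)))[1L]
  list(rsse = totals[hit], bks = combos[[hit]])
}

# a synthetic piecewise_fit for rule-logic tests (no data behind it)
make_fit <- function(slopes, phase, breakpoints = NULL,
                     breakpoint_pressures = NULL, n_points = 60L) {
  r <- length(slopes)
  if (is.null(breakpoints)) breakpoints <- seq_len(r - 1L) * 0.1
  if (is.null(breakpoint_pressures)) breakpoint_pressures <- rep(10, r - 1L)
  structure(list(r = r, breakpoints = breakpoints,
                 breakpoint_pressures = breakpoint_pressures,
                 breakpoint_index = seq_len(r - 1L) * 10L,
                 slopes = slopes, intercepts = rep(5, r), rsse = 0,
                 segment_sse = rep(0, r), n_points = n_points,
                 phase = phase, degenerate = FALSE),
            class = "piecewise_fit")
}

# a minimal breath_cycle carrier for rule-logic tests
make_rule_breath <- function(v_t = 0.45, peep = 5, end_gap = 0) {
  vol <- c(seq(0, v_t, length.out = 30), seq(v_t, end_gap, length.out = 30)[-1])
  structure(list(breath_index = 1L, time = seq_along(vol) * 0.01,
                 pressure = rep(10, length(vol)), flow = rep(0, length(vol)),
                 volume = vol, v_t = v_t, peep = peep,
                 peak_volume_index = 30L, start_index = 1L,
                 end_index = length(vol)),
            class = "breath_cycle")
}

# classify a single simulated breath through the fit/select/classify path
classify_sim_breath <- function(br, calib, cfg = rule_config()) {
  b <- breath_cycle(1L, br$time, br$pressure, br$flow,
                    integrate_volume(br$flow, br$time[2] - br$time[1]))
  h <- split_half_cycles(b, r_max = cfg$r_max)
  fi <- if (h$inspiration$fittable)
    select_model(h$inspiration, calib, cfg$alpha, cfg$r_max,
                 cfg$min_segment_points, cfg$max_candidates) else NULL
  fe <- if (h$expiration$fittable)
    select_model(h$expiration, calib, cfg$alpha, cfg$r_max,
                 cfg$min_segment_points, cfg$max_candidates) else NULL
  classify_breath(fi, fe, b, cfg)
}

# fixed variance calibration without running the calibration path
fixed_calib <- function(sigma2) {
  structure(list(sigma2 = sigma2, n_breaths_used = 1L, method = "mean",
                 floored = FALSE),
            class = "variance_calibration")
}
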