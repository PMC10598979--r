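#' Ordinary least-squares cost of a single segment
#'
#' Fits pressure on volume by ordinary least squares for one contiguous run of
#' half-cycle points and returns the slope (local elastance, cmH2O/L), the
#' pressure-axis intercept (cmH2O) and the residual sum of squared errors
#' (cmH2O^2). This is the inner term of the total piecewise residual that the
#' breakpoint search minimises.
#'
#' When all volumes in the segment coincide (a vertical run of points) the
#' slope is undefined; the segment is flagged degenerate, the intercept is the
#' mean pressure and the SSE is computed against that mean.
#'
#' @param volume numeric vector of volumes (L), length >= 2.
#' @param pressure numeric vector of pressures (cmH2O), same length.
#' @return list with elements `slope`, `intercept`, `sse`, `n`, `degenerate`.
#' @examples
#' seg <- segment_cost(c(0, 0.1, 0.2, 0.3), 5 + 10 * c(0, 0.1, 0.2, 0.3))
#' seg$slope      # 10
#' seg$sse        # 0
#' @export
segment_cost <- function(volume, pressure) {
  n <- length(volume)
  if (n < 2L || length(pressure) != n) {
    stop("segment_cost() needs >= 2 (volume, pressure) pairs of equal length",
         call. = FALSE)
  }
  vm <- mean(volume)
  pm <- mean(pressure)
  dv <- volume - vm
  dp <- pressure - pm
  sxx <- sum(dv * dv)
  # vertical segment: slope undefined, residuals measured against mean pressure
  if (sxx <= 1e-24 * max(1, vm * vm) * n) {
    return(list(slope = NA_real_, intercept = pm, sse = sum(dp * dp),
                n = n, degenerate = TRUE))
  }
  slope <- sum(dv * dp) / sxx
  intercept <- pm - slope * vm
  resid <- dp - slope * dv
  list(slope = slope, intercept = intercept, sse = sum(resid * resid),
       n = n, degenerate = FALSE)
}

# O(1) segment SSE over index range (a..b) from prefix sums.
# Returns the same quantity as segment_cost()$sse up to floating round-off;
# used only to locate the optimum, which is then re-scored with segment_cost().
.prefix_sums <- function(v, p) {
  list(sv  = cumsum(v),        sp  = cumsum(p),
       svv = cumsum(v * v),    spp = cumsum(p * p),
       svp = cumsum(v * p))
}

.range_sse <- function(ps, a, b) {
  # vectorised over a or b
  n  <- b - a + 1
  z  <- function(s) s[b] - ifelse(a > 1L, s[pmax(a - 1L, 1L)], 0)
  sv <- z(ps$sv); sp <- z(ps$sp)
  sxx <- z(ps$svv) - sv * sv / n
  syy <- z(ps$spp) - sp * sp / n
  sxy <- z(ps$svp) - sv * sp / n
  sse <- ifelse(sxx <= 1e-24 * pmax(1, (sv / n)^2) * n, syy,
                syy - sxy * sxy / sxx)
  pmax(sse, 0)
}

# Candidate segment-end indices for the breakpoint grid. All interior indices
# respecting the minimum segment length are candidates; above `max_candidates`
# the set is decimated to an evenly spaced subset (long half-cycles only).
.candidate_ends <- function(n, min_pts, max_candidates) {
  lo <- min_pts
  hi <- n - min_pts
  if (hi < lo) return(integer(0))
  cand <- lo:hi
  if (length(cand) > max_candidates) {
    cand <- unique(round(seq(lo, hi, length.out = max_candidates)))
  }
  as.integer(cand)
}

#' Fit an r-segment piecewise linear regression to a PV half-cycle
#'
#' Finds, over a grid of candidate breakpoints, the segmentation of the
#' half-cycle's ordered (volume, pressure) points into `r` contiguous runs
#' that minimises the total residual sum of squared errors (RSSE), fitting
#' each run by ordinary least squares. The search is exhaustive over the
#' candidate grid: a dynamic program over prefix segment costs visits every
#' admissible breakpoint combination, so the returned segmentation attains
#' the global grid minimum. Among combinations whose totals agree within
#' 1e-12 relative tolerance the lexicographically earliest (in traversal
#' order) is returned.
#'
#' Segments are contiguous index ranges in traversal order; segment i ends at
#' breakpoint i and segment i + 1 starts at the next sample. Breakpoints are
#' reported as the volumes of the data points ending each segment, with the
#' breakpoint pressure taken from the fitted line of the segment ending there.
#'
#' @param half a `half_cycle` (see [split_half_cycles()]), or any list with
#'   numeric `volume` and `pressure` of equal length.
#' @param r number of segments, >= 1.
#' @param min_segment_points minimum data points per segment (default 5,
#'   i.e. 50 ms at 100 Hz).
#' @param max_candidates cap on the number of candidate breakpoint positions
#'   (default 400; typical 100 Hz half-cycles are searched exhaustively).
#' @return an object of class `piecewise_fit`: list with `r`, `breakpoints`
#'   (volumes, length r - 1), `breakpoint_pressures`, `breakpoint_index`,
#'   `slopes`, `intercepts`, `rsse`, `n_points`, `phase`, `degenerate`.
#' @seealso [select_model()] for choosing `r` by the F-ratio cascade.
#' @export
fit_piecewise <- function(half, r, min_segment_points = 5L,
                          max_candidates = 400L) {
  v <- half$volume
  p <- half$pressure
  n <- length(v)
  r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1", call. = FALSE)
  if (n != length(p) || n < 2L) {
    stop("half-cycle needs volume and pressure of equal length >= 2",
         call. = FALSE)
  }
  m <- as.integer(min_segment_points)
  if (n < r * m) {
    stop(sprintf("half-cycle unfittable: %d points < %d segments x %d", n, r, m),
         call. = FALSE)
  }
  phase <- if (!is.null(half$phase)) half$phase else NA_character_

  if (r == 1L) {
    return(.build_fit(v, p, integer(0), phase))
  }

  ps <- .prefix_sums(v, p)
  cand <- .candidate_ends(n, m, max_candidates)
  if (length(cand) < r - 1L) {
    stop("half-cycle unfittable: too few candidate breakpoints", call. = FALSE)
  }

  # suffix dynamic program: suf[k, j] = min cost of covering points
  # (pos[j] + 1)..n with k segments whose ends lie on the candidate grid.
  pos <- c(0L, cand)                     # admissible segment starts - 1
  np <- length(pos)
  suf <- matrix(Inf, nrow = r, ncol = np)
  ok1 <- (n - pos) >= m
  suf[1, ok1] <- .range_sse(ps, pos[ok1] + 1L, n)
  if (r >= 2L) {
    for (k in 2:r) {
      # segment start pos[j]+1, end at candidate e: need e - pos[j] >= m and
      # suf[k-1] finite at e.
      prev <- suf[k - 1L, match(cand, pos)]
      for (j in seq_len(np)) {
        i <- pos[j]
        sel <- which(cand >= i + m & is.finite(prev))
        if (!length(sel)) next
        tot <- .range_sse(ps, i + 1L, cand[sel]) + prev[sel]
        suf[k, j] <- min(tot)
      }
    }
  }
  if (!is.finite(suf[r, 1L])) {
    stop("half-cycle unfittable at requested r under min_segment_points",
         call. = FALSE)
  }

  # forward reconstruction, lexicographically earliest within tolerance
  bks <- integer(r - 1L)
  i <- 0L
  for (k in r:2) {
    prev <- suf[k - 1L, match(cand, pos)]
    sel <- which(cand >= i + m & is.finite(prev))
    tot <- .range_sse(ps, i + 1L, cand[sel]) + prev[sel]
    best <- min(tot)
    tol <- 1e-12 * max(1, abs(best))
    j <- sel[which(tot <= best + tol)[1L]]
    bks[r - k + 1L] <- cand[j]
    i <- cand[j]
  }
  .build_fit(v, p, bks, phase)
}

# assemble a piecewise_fit by re-scoring each chosen segment with segment_cost,
# so RSSE is the plain left-to-right sum of per-segment OLS residuals
.build_fit <- function(v, p, bks, phase) {
  n <- length(v)
  bounds <- c(0L, bks, n)
  r <- length(bounds) - 1L
  slopes <- numeric(r)
  intercepts <- numeric(r)
  sses <- numeric(r)
  degen <- logical(r)
  for (s in seq_len(r)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    sc <- segment_cost(v[idx], p[idx])
    slopes[s] <- sc$slope
    intercepts[s] <- sc$intercept
    sses[s] <- sc$sse
    degen[s] <- sc$degenerate
  }
  bp_v <- v[bks]
  bp_p <- if (length(bks)) {
    vapply(seq_along(bks), function(i) {
      if (degen[i]) p[bks[i]] else slopes[i] * bp_v[i] + intercepts[i]
    }, numeric(1))
  } else numeric(0)
  structure(
    list(r = r, breakpoints = bp_v, breakpoint_pressures = bp_p,
         breakpoint_index = bks, slopes = slopes, intercepts = intercepts,
         rsse = sum(sses), segment_sse = sses, n_points = n, phase = phase,
         degenerate = any(degen)),
    class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("piecewise_fit: r = %d segments over %d points (%s)\n",
              x$r, x$n_points, ifelse(is.na(x$phase), "?", x$phase)))
  cat("  slopes (cmH2O/L):", paste(signif(x$slopes, 4), collapse = ", "), "\n")
  if (length(x$breakpoints)) {
    cat("  breakpoints (L):", paste(signif(x$breakpoints, 4), collapse = ", "), "\n")
  }
  cat(sprintf("  RSSE = %.6g cmH2O^2\n", x$rsse))
  invisible(x)
}

#' F-ratio between nested piecewise fits
#'
#' The improvement statistic F(r+1 | r) = (RSSE_r - RSSE_{r+1}) / sigma^2
#' comparing the r-segment null model against the (r+1)-segment alternative,
#' with sigma^2 the model variance calibrated from non-asynchronous breaths
#' (see [calibrate_variance()]). Clamped at zero if numerically negative.
#'
#' @param fit_r,fit_r_plus_1 `piecewise_fit`s of the same half-cycle with
#'   segment counts r and r + 1.
#' @param calib a `variance_calibration`.
#' @return the F-ratio (dimensionless, >= 0).
#' @export
f_ratio <- function(fit_r, fit_r_plus_1, calib) {
  if (fit_r_plus_1$r != fit_r$r + 1L) {
    stop("f_ratio() compares r against r + 1 segments", call. = FALSE)
  }
  if (fit_r_plus_1$n_points != fit_r$n_points) {
    stop("fits must be of the same half-cycle", call. = FALSE)
  }
  s2 <- calib$sigma2
  if (!is.numeric(s2) || length(s2) != 1L || !is.finite(s2) || s2 <= 0) {
    stop("calibration error: sigma2 must be a positive number", call. = FALSE)
  }
  max(0, (fit_r$rsse - fit_r_plus_1$rsse) / s2)
}

# Critical value for the F(r+1 | r) cascade. The improvement statistic spends
# two fitted parameters (slope, intercept) on the added segment, and the new
# breakpoint is optimised over n_cand candidate positions, so the per-position
# level is Bonferroni-adjusted: 2 * F_{1 - alpha/n_cand}(2, N - 2(r+1)).
# The df convention is a configurable knob recorded in run metadata.
critical_f <- function(n, r, alpha = 0.01, num_df = 2, den_df = NULL,
                       n_cand = 1L) {
  if (is.null(den_df)) den_df <- n - 2 * (r + 1)
  if (den_df < 1) return(Inf)
  num_df * stats::qf(1 - alpha / max(1L, n_cand), num_df, den_df)
}

#' Calibrate the model variance from non-asynchronous half-cycles
#'
#' Estimates sigma^2, the variance of the residual noise term of the piecewise
#' model, from half-cycles assumed non-asynchronous: each contributes its
#' two-segment RSSE divided by its residual degrees of freedom (N - 4), and
#' the estimates are pooled by the mean (default) or, robust to contamination
#' by undetected asynchronous breaths, the median. The result is floored at
#' 1e-6 cmH2O^2 (with a warning) so that noise-free synthetic data cannot
#' produce a degenerate divisor.
#'
#' @param halves list of `half_cycle`s (or lists with `volume`/`pressure`).
#' @param min_segment_points forwarded to [fit_piecewise()].
#' @param method `"mean"` (the calibration the method defines) or `"median"`
#'   (robust variant used by the record-level pipeline).
#' @return object of class `variance_calibration`: list with `sigma2`,
#'   `n_breaths_used`, `method`, `floored`.
#' @export
calibrate_variance <- function(halves, min_segment_points = 5L,
                               method = c("mean", "median")) {
  method <- match.arg(method)
  if (!length(halves)) stop("calibration error: no half-cycles", call. = FALSE)
  vals <- numeric(0)
  for (h in halves) {
    n <- length(h$volume)
    if (n < max(2L * min_segment_points, 5L)) next
    fit <- tryCatch(fit_piecewise(h, 2L, min_segment_points), error = function(e) NULL)
    if (is.null(fit)) next
    vals <- c(vals, fit$rsse / (n - 4))
  }
  if (!length(vals)) {
    stop("calibration error: all half-cycles unfittable", call. = FALSE)
  }
  s2 <- if (method == "mean") mean(vals) else stats::median(vals)
  floored <- FALSE
  if (s2 < 1e-6) {
    warning("calibrated sigma2 below floor; using 1e-6 cmH2O^2", call. = FALSE)
    s2 <- 1e-6
    floored <- TRUE
  }
  structure(list(sigma2 = s2, n_breaths_used = length(vals), method = method,
                 floored = floored),
            class = "variance_calibration")
}

#' @export
print.variance_calibration <- function(x, ...) {
  cat(sprintf("variance_calibration: sigma2 = %.6g cmH2O^2 (%s of %d half-cycles%s)\n",
              x$sigma2, x$method, x$n_breaths_used,
              if (x$floored) ", floored" else ""))
  invisible(x)
}

#' Select the segment count of a half-cycle by the F-ratio cascade
#'
#' Starting from the two-segment model that a non-asynchronous half-cycle is
#' assumed to follow, iteratively tests r segments (null) against r + 1
#' (alternative): if the F-ratio falls below the critical value the null is
#' accepted and the r-segment fit returned; otherwise r is incremented, up to
#' `r_max`.
#'
#' @param half a `half_cycle`.
#' @param calib a `variance_calibration` supplying sigma^2.
#' @param alpha significance level of each test (default 0.01).
#' @param r_max largest segment count considered (default 5; 2..7 supported).
#' @param min_segment_points,max_candidates forwarded to [fit_piecewise()].
#' @return the accepted `piecewise_fit`, with attribute `"f_trace"` recording
#'   the tested F-ratios and critical values.
#' @export
select_model <- function(half, calib, alpha = 0.01, r_max = 5L,
                         min_segment_points = 5L, max_candidates = 400L) {
  r_max <- as.integer(r_max)
  if (r_max < 2L || r_max > 7L) stop("r_max must be in 2..7", call. = FALSE)
  n <- length(half$volume)
  fit <- fit_piecewise(half, 2L, min_segment_points, max_candidates)
  trace <- list()
  r <- 2L
  while (r < r_max) {
    if (n < (r + 1L) * min_segment_points) break
    fit_next <- tryCatch(
      fit_piecewise(half, r + 1L, min_segment_points, max_candidates),
      error = function(e) NULL)
    if (is.null(fit_next)) break
    f <- f_ratio(fit, fit_next, calib)
    n_cand <- length(.candidate_ends(n, min_segment_points, max_candidates))
    crit <- critical_f(n, r, alpha, n_cand = n_cand)
    trace[[length(trace) + 1L]] <- c(r = r, F = f, crit = crit)
    if (f < crit) break
    fit <- fit_next
    r <- r + 1L
  }
  attr(fit, "f_trace") <- trace
  fit
}

#' Serialise a piecewise fit to a plain list (for JSON output)
#' @param fit a `piecewise_fit`.
#' @return list of plain vectors suitable for [jsonlite::toJSON()].
#' @export
fit_to_list <- function(fit) {
  list(r = fit$r, phase = fit$phase, breakpoints = fit$breakpoints,
       breakpoint_pressures = fit$breakpoint_pressures,
       slopes = fit$slopes, intercepts = fit$intercepts,
       rsse = fit$rsse, n_points = fit$n_points)
}
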