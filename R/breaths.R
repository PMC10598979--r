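#' Construct a breath cycle
#'
#' One ventilated breath with its per-sample traces. Volume is baselined to
#' zero at the breath's first sample; tidal volume is the maximum of the
#' baselined trace; PEEP is estimated as the pressure at the breath's first
#' sample (start-of-inspiration baseline, available per breath without
#' look-back).
#'
#' @param breath_index ordinal of the breath within its record.
#' @param time,pressure,flow,volume per-sample traces; `volume[1]` must be 0.
#' @param start_index,end_index sample range within the parent record.
#' @return object of class `breath_cycle` with additional fields `v_t`
#'   (tidal volume, L), `peep` (cmH2O) and `peak_volume_index`.
#' @export
breath_cycle <- function(breath_index, time, pressure, flow, volume,
                         start_index = NA_integer_, end_index = NA_integer_) {
  n <- length(time)
  if (n < 2L) stop("data error: breath needs >= 2 samples", call. = FALSE)
  stopifnot(length(pressure) == n, length(flow) == n, length(volume) == n)
  if (abs(volume[1]) > 1e-9) {
    stop("data error: breath volume must be baselined to 0 at start",
         call. = FALSE)
  }
  v_t <- max(volume)
  if (!(v_t > 0)) stop("data error: non-positive tidal volume", call. = FALSE)
  peak <- which.max(volume)   # first sample attaining the maximum
  structure(list(breath_index = as.integer(breath_index), time = time,
                 pressure = pressure, flow = flow, volume = volume,
                 v_t = v_t, peep = pressure[1],
                 peak_volume_index = as.integer(peak),
                 start_index = as.integer(start_index),
                 end_index = as.integer(end_index)),
            class = "breath_cycle")
}

#' @export
print.breath_cycle <- function(x, ...) {
  cat(sprintf(
    "breath_cycle #%d: %d samples, V_T = %.3f L, PEEP = %.2f cmH2O, peak at %d\n",
    x$breath_index, length(x$time), x$v_t, x$peep, x$peak_volume_index))
  invisible(x)
}

#' Segment a waveform record into breaths
#'
#' Inspiration onset is detected as flow rising above `onset_threshold`
#' (clearly inspiratory), sustained for at least `min_insp_duration`, with
#' near-zero flow (<= `flow_threshold`) somewhere in the 3-sample look-back
#' window; the onset is placed at the crossing sample itself, so noisy
#' near-zero samples from the preceding expiratory tail are never absorbed
#' into the breath. Each breath runs from its onset to the sample before the
#' next onset; volume is integrated from flow (trapezoidal) unless the
#' record carries a volume column, and re-baselined to zero at each breath
#' start.
#'
#' Two robustness rules documented in the methods vignette: a candidate
#' breath whose end volume exceeds `merge_frac` of its tidal volume has not
#' completed exhalation (the double-trigger pattern) and is merged with the
#' following candidate; candidate breaths with tidal volume below `vt_min`
#' (noise artifacts) are dropped.
#'
#' @param record a [waveform_record()].
#' @param min_insp_duration sustained positive-flow duration (s, default 0.05).
#' @param flow_threshold near-zero flow threshold (L/s, default 0.01).
#' @param onset_threshold clearly-inspiratory flow threshold (L/s,
#'   default 0.05).
#' @param merge_frac incomplete-exhalation merge threshold (default 0.3).
#' @param vt_min minimum tidal volume to keep a breath (L, default 0.02).
#' @return list of [breath_cycle()]s (possibly empty).
#' @export
segment_breaths <- function(record, min_insp_duration = 0.05,
                            flow_threshold = 0.01, onset_threshold = 0.05,
                            merge_frac = 0.3, vt_min = 0.02) {
  stopifnot(inherits(record, "waveform_record"))
  flow <- record$flow
  n <- length(flow)
  dt <- 1 / record$sample_rate
  k <- max(1L, as.integer(round(min_insp_duration / dt)))

  above <- flow > onset_threshold
  # remaining run length of above-threshold samples starting at each sample
  r <- rle(above)
  runlen <- unlist(lapply(seq_along(r$lengths), function(j) {
    if (r$values[j]) r$lengths[j]:1 else rep(0L, r$lengths[j])
  }), use.names = FALSE)
  # onset: sustained rise above the inspiratory threshold, with near-zero
  # flow in the 3-sample look-back window (robust to noise around the
  # expiratory tail); candidates closer than 10 samples collapse to the first
  lag1 <- c(Inf, flow[-n])
  lag2 <- c(Inf, lag1[-n])
  lag3 <- c(Inf, lag2[-n])
  prev_min <- pmin(lag1, lag2, lag3)
  onset <- which(above & runlen >= k & prev_min <= flow_threshold)
  if (!length(onset)) return(list())
  onset <- onset[c(TRUE, diff(onset) > 10L)]

  starts <- onset
  ends <- c(onset[-1] - 1L, n)
  volume <- if (!is.null(record$volume)) record$volume else
    integrate_volume(flow, dt)

  # merge candidates whose exhalation did not complete (double-trigger pattern)
  i <- 1L
  keep_s <- integer(0); keep_e <- integer(0)
  while (i <= length(starts)) {
    s <- starts[i]; e <- ends[i]
    while (i < length(starts)) {
      vol_rel <- volume[s:e] - volume[s]
      if (max(vol_rel) > 0 &&
          vol_rel[length(vol_rel)] > merge_frac * max(vol_rel)) {
        i <- i + 1L
        e <- ends[i]
      } else break
    }
    keep_s <- c(keep_s, s); keep_e <- c(keep_e, e)
    i <- i + 1L
  }

  breaths <- list()
  bi <- 0L
  for (j in seq_along(keep_s)) {
    idx <- keep_s[j]:keep_e[j]
    vol_rel <- volume[idx] - volume[idx[1]]
    if (length(idx) < 2L || max(vol_rel) < vt_min) next
    bi <- bi + 1L
    breaths[[bi]] <- breath_cycle(bi, record$time[idx], record$pressure[idx],
                                  record$flow[idx], vol_rel,
                                  keep_s[j], keep_e[j])
  }
  breaths
}

#' Split a breath's PV loop into inspiratory and expiratory half-cycles
#'
#' The loop is divided at the turning point of maximum volume: inspiration is
#' samples 1..peak, expiration is samples peak..end (the peak sample belongs
#' to both halves), each in traversal order. A half with fewer than
#' `2 * (r_max + 1)` points - or a degenerate peak at the first or last
#' sample - is flagged unfittable rather than erroring.
#'
#' @param breath a [breath_cycle()].
#' @param r_max largest segment count the downstream fit will consider
#'   (default 5); sets the fitting-eligibility point count.
#' @return list with elements `inspiration` and `expiration`, each of class
#'   `half_cycle`: fields `phase`, `volume`, `pressure`, `n_points`,
#'   `fittable`, `breath_index`.
#' @export
split_half_cycles <- function(breath, r_max = 5L) {
  stopifnot(inherits(breath, "breath_cycle"))
  peak <- breath$peak_volume_index
  n <- length(breath$volume)
  min_n <- 2L * (as.integer(r_max) + 1L)
  mk <- function(idx, phase) {
    structure(list(phase = phase,
                   volume = breath$volume[idx], pressure = breath$pressure[idx],
                   n_points = length(idx),
                   fittable = length(idx) >= min_n,
                   breath_index = breath$breath_index),
              class = "half_cycle")
  }
  list(inspiration = mk(1:peak, "inspiration"),
       expiration  = mk(peak:n, "expiration"))
}

#' @export
print.half_cycle <- function(x, ...) {
  cat(sprintf("half_cycle (%s), breath #%s: %d points, V %.3f..%.3f L%s\n",
              x$phase, x$breath_index, x$n_points, min(x$volume),
              max(x$volume), if (x$fittable) "" else " [unfittable]"))
  invisible(x)
}
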