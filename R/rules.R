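#' Configuration of the asynchrony classification rules
#'
#' @param epsilon auto-triggering volume-gap threshold (L); `NA` (default)
#'   uses `epsilon_rel * V_T` per breath.
#' @param epsilon_rel relative gap threshold as a fraction of tidal volume
#'   (default 0.1), used when `epsilon` is `NA`.
#' @param dc_slope_factor delayed-cycling slope factor: the final inspiratory
#'   elastance must exceed `dc_slope_factor` times the preceding one
#'   (default 2).
#' @param precedence order in which matched rules resolve to the primary
#'   label; inspiratory rules first, auto triggering last.
#' @param relaxed_fa also accept the 3-segment flow-asynchrony variant
#'   (clear early-inspiratory pressure drop with one fewer recovery
#'   segment); off by default.
#' @param alpha,r_max,min_segment_points,max_candidates model-selection
#'   settings forwarded by the record-level pipeline.
#' @return object of class `rule_config`.
#' @export
rule_config <- function(epsilon = NA_real_, epsilon_rel = 0.1,
                        dc_slope_factor = 2,
                        precedence = c("dt", "dc", "fa", "rt", "pc", "ie", "at"),
                        relaxed_fa = FALSE, alpha = 0.01, r_max = 5L,
                        min_segment_points = 5L, max_candidates = 400L) {
  if (!is.na(epsilon) && epsilon <= 0) {
    stop("config error: epsilon must be > 0", call. = FALSE)
  }
  if (epsilon_rel <= 0) stop("config error: epsilon_rel must be > 0", call. = FALSE)
  if (dc_slope_factor <= 1) {
    stop("config error: dc_slope_factor must be > 1", call. = FALSE)
  }
  if (!setequal(precedence, asynchrony_types())) {
    stop("config error: precedence must order the seven type codes",
         call. = FALSE)
  }
  structure(list(epsilon = epsilon, epsilon_rel = epsilon_rel,
                 dc_slope_factor = dc_slope_factor, precedence = precedence,
                 relaxed_fa = relaxed_fa, alpha = alpha,
                 r_max = as.integer(r_max),
                 min_segment_points = as.integer(min_segment_points),
                 max_candidates = as.integer(max_candidates)),
            class = "rule_config")
}

# helper predicates on a fit; all comparisons fail cleanly on NA slopes
.sgn <- function(x, pos) !is.na(x) & if (pos) x > 0 else x < 0

#' Evaluate one asynchrony rule against a breath's fitted half-cycles
#'
#' Each of the seven types is a predicate on the segment count, slope signs,
#' breakpoint volumes/pressures of one half-cycle's piecewise fit (plus
#' breath context: tidal volume V_T and PEEP). Phase assignment: fa, rt, dc
#' and dt inspect the inspiratory fit; pc and ie the expiratory; at both.
#' An unfittable (NULL) fit for the inspected phase yields `FALSE` with
#' `"unfittable"` evidence, never an error.
#'
#' Signatures (slopes k_s in traversal order, r = segment count):
#' \describe{
#'   \item{fa}{inspiration: r = 4, signs (+,-,+,+), and not the dc condition.}
#'   \item{rt}{inspiration: r = 4, signs (+,+,-,+).}
#'   \item{pc}{expiration: r = 4, signs (+,-,+,+), first breakpoint within
#'     V_T/2 of the expiratory start.}
#'   \item{dt}{inspiration: r = 5, k1 > 0, k1 > k2, k3 > k2, k4 > k5,
#'     P(N3) < PEEP, P(N2) > P(N3), P(N4) > P(N3).}
#'   \item{dc}{inspiration: r = 4, signs (+,-,+,+), k4 > factor * k3.}
#'   \item{ie}{expiration: r = 4, signs (+,+,-,+), second breakpoint more
#'     than V_T/2 below the expiratory start.}
#'   \item{at}{both halves r = 2 with all slopes > 0 and end-expiratory
#'     volume more than epsilon above the breath's baseline.}
#' }
#'
#' @param label asynchrony type code.
#' @param insp,exp_ `piecewise_fit`s of the inspiratory and expiratory
#'   half-cycles (either may be `NULL` if unfittable).
#' @param breath the [breath_cycle()] providing V_T and PEEP.
#' @param cfg a [rule_config()].
#' @return list with `matched` (logical) and `evidence` (named values the
#'   predicate inspected).
#' @export
evaluate_rule <- function(label, insp, exp_, breath, cfg = rule_config()) {
  label <- match.arg(label, asynchrony_types())
  phase_fit <- switch(label,
                      fa = , rt = , dt = , dc = insp,
                      pc = , ie = exp_,
                      at = NULL)
  if (label != "at" && is.null(phase_fit)) {
    return(list(matched = FALSE, evidence = list(unfittable = TRUE)))
  }
  k <- if (!is.null(phase_fit)) phase_fit$slopes else NULL
  v_t <- breath$v_t
  ev <- list()

  matched <- switch(label,
    fa = {
      ok4 <- phase_fit$r == 4L && .sgn(k[1], TRUE) && .sgn(k[2], FALSE) &&
        .sgn(k[3], TRUE) && .sgn(k[4], TRUE) &&
        !(k[4] > cfg$dc_slope_factor * k[3])
      ok3 <- cfg$relaxed_fa && phase_fit$r == 3L && .sgn(k[1], TRUE) &&
        .sgn(k[2], FALSE) && .sgn(k[3], TRUE)
      ev <- list(r = phase_fit$r, slopes = k,
                 dc_excluded = phase_fit$r == 4L &&
                   isTRUE(k[4] > cfg$dc_slope_factor * k[3]))
      isTRUE(ok4) || isTRUE(ok3)
    },
    rt = {
      ev <- list(r = phase_fit$r, slopes = k)
      phase_fit$r == 4L && .sgn(k[1], TRUE) && .sgn(k[2], TRUE) &&
        .sgn(k[3], FALSE) && .sgn(k[4], TRUE)
    },
    pc = {
      # expiratory N0 is the first expiratory point (volume = V_T), so
      # V(N0) - V(N1) is the positive volume drop to the first breakpoint
      drop1 <- if (length(phase_fit$breakpoints))
        v_t - phase_fit$breakpoints[1] else NA_real_
      ev <- list(r = phase_fit$r, slopes = k, v_drop_to_N1 = drop1,
                 half_vt = v_t / 2)
      phase_fit$r == 4L && .sgn(k[1], TRUE) && .sgn(k[2], FALSE) &&
        .sgn(k[3], TRUE) && .sgn(k[4], TRUE) &&
        !is.na(drop1) && drop1 < v_t / 2
    },
    dt = {
      bp <- phase_fit$breakpoint_pressures
      ev <- list(r = phase_fit$r, slopes = k, breakpoint_pressures = bp,
                 peep = breath$peep)
      phase_fit$r == 5L && .sgn(k[1], TRUE) &&
        !anyNA(k) && k[1] > k[2] && k[3] > k[2] && k[4] > k[5] &&
        length(bp) == 4L && bp[3] < breath$peep && bp[2] > bp[3] &&
        bp[4] > bp[3]
    },
    dc = {
      ev <- list(r = phase_fit$r, slopes = k, factor = cfg$dc_slope_factor)
      phase_fit$r == 4L && .sgn(k[1], TRUE) && .sgn(k[2], FALSE) &&
        .sgn(k[3], TRUE) && .sgn(k[4], TRUE) &&
        k[4] > cfg$dc_slope_factor * k[3]
    },
    ie = {
      drop2 <- if (length(phase_fit$breakpoints) >= 2L)
        v_t - phase_fit$breakpoints[2] else NA_real_
      ev <- list(r = phase_fit$r, slopes = k, v_drop_to_N2 = drop2,
                 half_vt = v_t / 2)
      phase_fit$r == 4L && .sgn(k[1], TRUE) && .sgn(k[2], TRUE) &&
        .sgn(k[3], FALSE) && .sgn(k[4], TRUE) &&
        !is.na(drop2) && drop2 > v_t / 2
    },
    at = {
      if (is.null(insp) || is.null(exp_)) {
        ev <- list(unfittable = TRUE)
        FALSE
      } else {
        eps <- if (is.na(cfg$epsilon)) cfg$epsilon_rel * v_t else cfg$epsilon
        gap <- breath$volume[length(breath$volume)]  # end-expiratory volume
        ev <- list(r_insp = insp$r, r_exp = exp_$r,
                   slopes_insp = insp$slopes, slopes_exp = exp_$slopes,
                   volume_gap = gap, epsilon = eps)
        insp$r == 2L && exp_$r == 2L &&
          all(.sgn(insp$slopes, TRUE)) && all(.sgn(exp_$slopes, TRUE)) &&
          gap > eps
      }
    })
  list(matched = isTRUE(matched), evidence = ev)
}

#' Classify one breath from its fitted half-cycles
#'
#' Evaluates all seven type predicates and resolves the primary label as the
#' first match in the configured precedence order (`none` if no predicate
#' holds, or if both halves are unfittable).
#'
#' @param insp,exp_ `piecewise_fit`s (or `NULL` when unfittable).
#' @param breath the [breath_cycle()].
#' @param cfg a [rule_config()].
#' @return object of class `breath_classification`: list with
#'   `breath_index`, `primary_label`, `matched_rules`, `evidence`,
#'   `insp_fit`, `exp_fit`.
#' @export
classify_breath <- function(insp, exp_, breath, cfg = rule_config()) {
  res <- lapply(stats::setNames(nm = cfg$precedence), function(lb)
    evaluate_rule(lb, insp, exp_, breath, cfg))
  matched <- names(res)[vapply(res, `[[`, logical(1), "matched")]
  primary <- if (length(matched)) matched[1] else "none"
  structure(list(breath_index = breath$breath_index,
                 primary_label = primary, matched_rules = matched,
                 evidence = lapply(res, `[[`, "evidence"),
                 insp_fit = insp, exp_fit = exp_),
            class = "breath_classification")
}

#' @export
print.breath_classification <- function(x, ...) {
  cat(sprintf("breath #%d: %s%s\n", x$breath_index, x$primary_label,
              if (length(x$matched_rules) > 1)
                paste0(" (also matched: ",
                       paste(setdiff(x$matched_rules, x$primary_label),
                             collapse = ", "), ")") else ""))
  invisible(x)
}

#' Run the full detection pipeline over a waveform record
#'
#' Segments the record into breaths, splits each PV loop at peak volume,
#' calibrates the model variance, selects each half-cycle's segment count by
#' the F-ratio cascade and classifies every breath.
#'
#' Calibration: the two-segment residual variance RSSE/(N - 4) is pooled
#' over the half-cycles of the first `n_calib` breaths with the median
#' (robust to asynchronous breaths contaminating the window); pass an
#' explicit `calib` to override.
#'
#' @param record a [waveform_record()].
#' @param cfg a [rule_config()].
#' @param calib optional `variance_calibration`; `NULL` calibrates from the
#'   record itself.
#' @param n_calib breaths in the calibration window (default 20).
#' @return object of class `asynchrony_result`: list with `classifications`
#'   (list of `breath_classification`), `labels` (character vector),
#'   `breaths`, `calibration` and `config`.
#' @export
classify_record <- function(record, cfg = rule_config(), calib = NULL,
                            n_calib = 20L) {
  breaths <- segment_breaths(record)
  if (!length(breaths)) {
    warning("no breaths detected", call. = FALSE)
    return(structure(list(classifications = list(), labels = character(0),
                          breaths = list(), calibration = calib, config = cfg),
                     class = "asynchrony_result"))
  }
  halves <- lapply(breaths, split_half_cycles, r_max = cfg$r_max)
  if (is.null(calib)) {
    ch <- unlist(lapply(halves[seq_len(min(n_calib, length(halves)))],
                        function(h) list(h$inspiration, h$expiration)),
                 recursive = FALSE)
    ch <- Filter(function(h) h$fittable, ch)
    calib <- calibrate_variance(ch, cfg$min_segment_points, method = "median")
  }
  cls <- vector("list", length(breaths))
  for (i in seq_along(breaths)) {
    h <- halves[[i]]
    fit1 <- if (h$inspiration$fittable)
      select_model(h$inspiration, calib, cfg$alpha, cfg$r_max,
                   cfg$min_segment_points, cfg$max_candidates) else NULL
    fit2 <- if (h$expiration$fittable)
      select_model(h$expiration, calib, cfg$alpha, cfg$r_max,
                   cfg$min_segment_points, cfg$max_candidates) else NULL
    cls[[i]] <- classify_breath(fit1, fit2, breaths[[i]], cfg)
  }
  structure(list(classifications = cls,
                 labels = vapply(cls, `[[`, character(1), "primary_label"),
                 breaths = breaths, calibration = calib, config = cfg),
            class = "asynchrony_result")
}

#' @export
print.asynchrony_result <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("asynchrony_result: %d breaths\n", n))
  if (n) {
    tab <- table(factor(x$labels, levels = c(asynchrony_types(), "none")))
    print(tab)
    cat(sprintf("asynchrony index: %.3f\n", mean(x$labels != "none")))
  }
  invisible(x)
}
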