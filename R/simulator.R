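#' Simulator configuration for ventilated breaths
#'
#' Single-compartment respiratory mechanics driving a volume-controlled (VC)
#' or pressure-controlled (PC) breath: airway pressure follows
#' P = E.V + R.Q + PEEP - Pmus, with a two-regime (sigmoid-like) elastance
#' so that a normal half-cycle is a two-segment PV polyline divided by its
#' inflection point. Patient-effort distortions are injected as
#' piecewise-linear deviations of the PV limbs (see [effort_event()]), so a
#' noise-free archetype is an exact polyline with a well-defined segment
#' count - the ground truth the detection pipeline is evaluated against.
#'
#' @param mode `"VC"` (square inspiratory flow) or `"PC"` (prescribed
#'   pressure, first-order volume response). The `preset` argument installs
#'   the shipped mode presets: `"VC-AC"` (default) and `"PC-SIMV"`; `"PSV"`
#'   approximates pressure support as PC with flow-cycled expiration and is
#'   experimental.
#' @param e1,e2 elastance below/above the inflection volume (cmH2O/L).
#' @param v_infl inflection volume of the two-regime elastance (L).
#' @param resistance airway resistance (cmH2O.s/L).
#' @param peep set positive end-expiratory pressure (cmH2O).
#' @param rate respiratory rate (breaths/min).
#' @param ie_ratio expiratory:inspiratory time ratio (2 means I:E = 1:2).
#' @param tidal_volume VC tidal target (L).
#' @param pressure_target PC driving pressure above PEEP (cmH2O).
#' @param sample_rate sampling rate (Hz).
#' @param noise_sd_pressure,noise_sd_flow additive i.i.d. Gaussian
#'   measurement noise (cmH2O, L/s).
#' @param seed optional integer seed making [simulate_breath()] reproducible.
#' @param preset optional mode preset name.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(mode = c("VC", "PC"), e1 = 12, e2 = 20, v_infl = 0.22,
                       resistance = 8, peep = 5, rate = 15, ie_ratio = 2,
                       tidal_volume = 0.45, pressure_target = 12,
                       sample_rate = 100, noise_sd_pressure = 0.2,
                       noise_sd_flow = 0.01, seed = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("VC-AC", "PC-SIMV", "PSV"))
    mode <- switch(preset, "VC-AC" = "VC", "PC-SIMV" = "PC", "PSV" = "PC")
  } else {
    mode <- match.arg(mode)
    preset <- NA_character_
  }
  stopifnot(e1 > 0, e2 > 0, resistance > 0, rate > 0, sample_rate > 0,
            noise_sd_pressure >= 0, noise_sd_flow >= 0, peep >= 0,
            tidal_volume > 0, ie_ratio > 0)
  structure(list(mode = mode, e1 = e1, e2 = e2, v_infl = v_infl,
                 resistance = resistance, peep = peep, rate = rate,
                 ie_ratio = ie_ratio, tidal_volume = tidal_volume,
                 pressure_target = pressure_target, sample_rate = sample_rate,
                 noise_sd_pressure = noise_sd_pressure,
                 noise_sd_flow = noise_sd_flow, seed = seed, preset = preset),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %s mode, E = %g/%g cmH2O/L, R = %g, PEEP = %g, %g/min, I:E = 1:%g\n",
    x$mode, x$e1, x$e2, x$resistance, x$peep, x$rate, x$ie_ratio))
  invisible(x)
}

#' Patient-effort event injected into a simulated breath
#'
#' Describes the distortion that turns a normal breath into one of the seven
#' asynchrony archetypes. `amplitude` scales the pressure deviation of the
#' effort (and, for auto triggering, the circuit-leak volume); `onset` and
#' `duration` default to type-specific placements chosen so the archetype's
#' PV signature is geometrically guaranteed at zero noise.
#'
#' @param target_label one of `"fa"`, `"rt"`, `"pc"`, `"dt"`, `"dc"`,
#'   `"ie"`, `"at"`.
#' @param amplitude effort pressure amplitude (cmH2O, default 4).
#' @param onset fraction of the breath cycle at which the effort starts
#'   (`NA` = type default).
#' @param duration effort duration in seconds (`NA` = type default).
#' @param leak_rate circuit leak (L/s; `at` only; `NA` derives the leak
#'   volume from `amplitude` as 0.05 * amplitude * V_T).
#' @param extra_trigger whether a second ventilator cycle is delivered
#'   (`dt` only; `TRUE` by default for `dt`).
#' @return object of class `effort_event`.
#' @export
effort_event <- function(target_label, amplitude = 4, onset = NA_real_,
                         duration = NA_real_, leak_rate = NA_real_,
                         extra_trigger = NULL) {
  target_label <- match.arg(target_label, asynchrony_types())
  if (!is.na(onset) && (onset < 0 || onset >= 1)) {
    stop("config error: onset must be in [0, 1)", call. = FALSE)
  }
  if (amplitude < 0) stop("config error: amplitude must be >= 0", call. = FALSE)
  if (is.null(extra_trigger)) extra_trigger <- identical(target_label, "dt")
  if (identical(target_label, "dt") && !extra_trigger) {
    stop("config error: dt requires extra_trigger = TRUE", call. = FALSE)
  }
  structure(list(target_label = target_label, amplitude = amplitude,
                 onset = onset, duration = duration, leak_rate = leak_rate,
                 extra_trigger = extra_trigger),
            class = "effort_event")
}

#' The seven asynchrony type codes
#' @return character vector `c("fa","rt","pc","dt","dc","ie","at")`.
#' @export
asynchrony_types <- function() c("fa", "rt", "pc", "dt", "dc", "ie", "at")

# ---- internal geometry ------------------------------------------------------

# two-regime elastic recoil pressure (cmH2O) at volume v
.pel <- function(v, cfg) {
  ifelse(v <= cfg$v_infl, cfg$e1 * v,
         cfg$e1 * cfg$v_infl + cfg$e2 * (v - cfg$v_infl))
}

# inspiratory base PV line as a function of volume, plus its polyline vertices
.insp_base <- function(cfg) {
  vt <- cfg$tidal_volume
  if (cfg$mode == "VC") {
    ti <- (60 / cfg$rate) / (1 + cfg$ie_ratio)
    q <- vt / ti
    p0 <- cfg$peep + cfg$resistance * q
    f <- function(v) p0 + .pel(v, cfg)
    verts <- cbind(v = c(0, min(cfg$v_infl, vt), vt),
                   p = f(c(0, min(cfg$v_infl, vt), vt)))
  } else {
    # imperfect pressurisation ramp: quick rise then plateau creep
    dp <- cfg$pressure_target
    vk <- 0.25 * vt
    f <- function(v) {
      ifelse(v <= vk,
             cfg$peep + 0.70 * dp + 0.25 * dp * v / vk,
             cfg$peep + 0.95 * dp + 0.05 * dp * (v - vk) / (vt - vk))
    }
    verts <- cbind(v = c(0, vk, vt), p = f(c(0, vk, vt)))
  }
  list(f = f, vertices = verts)
}

# expiratory base polyline from (v_t, ptop) down to (gap, peep)
.exp_base_vertices <- function(cfg, v_t, ptop, gap = 0) {
  vm <- gap + (min(cfg$v_infl, 0.6 * v_t) / v_t) * (v_t - gap)
  pm <- cfg$peep + 0.16 * (ptop - cfg$peep)
  cbind(v = c(gap, vm, v_t), p = c(cfg$peep, pm, ptop))
}

.interp_poly <- function(verts, v) {
  stats::approx(verts[, "v"], verts[, "p"], xout = v, rule = 2)$y
}

# archetype vertex geometry. Returns insp/exp vertex matrices plus, for dt,
# an explicit phase plan. All deviations are piecewise-linear in PV space.
.archetype_geometry <- function(cfg, event) {
  vt <- cfg$tidal_volume
  a <- if (is.null(event)) 0 else event$amplitude
  label <- if (is.null(event)) "none" else event$target_label
  base <- .insp_base(cfg)
  f <- base$f
  insp <- base$vertices
  gap <- 0

  if (label == "fa") {
    v <- c(0, 0.18 * vt, 0.35 * vt, 0.667 * vt, vt)
    p <- f(v); p[3] <- p[3] - a
    insp <- cbind(v = v, p = p)
  } else if (label == "dc") {
    v <- c(0, 0.18 * vt, 0.35 * vt, 0.844 * vt, vt)
    p <- f(v); p[3] <- p[3] - a
    spike <- (1 + a) * cfg$e2            # end-inspiratory pressure spike
    p[5] <- p[4] + spike * (v[5] - v[4])
    insp <- cbind(v = v, p = p)
  } else if (label == "rt") {
    # delayed (ventilator-triggered) effort: sag late in insufflation
    v <- c(0, min(cfg$v_infl, 0.5 * vt), 0.82 * vt, 0.93 * vt, vt)
    p <- f(v)
    p[4] <- p[4] - a
    insp <- cbind(v = v, p = p)
  }

  ptop <- insp[nrow(insp), "p"]
  if (label == "at") {
    gap <- if (!is.null(event) && !is.na(event$leak_rate)) {
      te <- (60 / cfg$rate) * cfg$ie_ratio / (1 + cfg$ie_ratio)
      min(event$leak_rate * te, 0.6 * vt)
    } else min(0.05 * a * vt, 0.6 * vt)
    expv <- .exp_base_vertices(cfg, vt, ptop, gap)
  } else if (label == "pc") {
    bb <- .exp_base_vertices(cfg, vt, ptop)
    v <- c(0, bb[2, "v"], 0.689 * vt, 0.867 * vt, vt)
    p <- c(cfg$peep, bb[2, "p"], ptop - 0.7 * a, ptop - 1.2 * a, ptop)
    expv <- cbind(v = v, p = p)
  } else if (label == "ie") {
    bb <- .exp_base_vertices(cfg, vt, ptop)
    pexp <- function(v) .interp_poly(bb, v)
    v <- c(0, 0.2 * vt, 0.333 * vt, bb[2, "v"], vt)
    p <- c(cfg$peep, pexp(0.2 * vt), pexp(0.333 * vt) - a, bb[2, "p"], ptop)
    expv <- cbind(v = v, p = p)
  } else {
    expv <- .exp_base_vertices(cfg, vt, ptop)
  }
  list(insp_vertices = insp, exp_vertices = expv, gap = gap, label = label)
}

# volume profile helpers --------------------------------------------------

# inspiratory volume at local sample times t (0..ti)
.insp_volume <- function(cfg, t, ti, vt) {
  if (cfg$mode == "VC") {
    vt * t / ti
  } else {
    tau <- ti / 3
    vt * (1 - exp(-t / tau)) / (1 - exp(-ti / tau))
  }
}

# flow consistent with cumulative trapezoidal integration of volume
.flow_from_volume <- function(v, dt) {
  n <- length(v)
  f <- numeric(n)
  f[1] <- (v[2] - v[1]) / dt
  for (i in 2:n) f[i] <- 2 * (v[i] - v[i - 1]) / dt - f[i - 1]
  f
}

#' Simulate one ventilated breath
#'
#' Builds the clean pressure/flow/volume traces of a single breath - normal,
#' or distorted into the archetype named by `event` - then adds Gaussian
#' measurement noise. At zero noise the breath's PV half-cycles are exact
#' polylines whose segment structure matches the archetype's defining sign
#' pattern, and the emitted flow integrates (trapezoidally) back to the
#' volume trace exactly.
#'
#' @param cfg a [sim_config()]; if `cfg$seed` is set the waveform is
#'   bit-reproducible.
#' @param event an [effort_event()] or `NULL` for a normal breath.
#' @return list with `time`, `pressure`, `flow`, `volume` (clean, baselined),
#'   `true_label`, and `n` (sample count).
#' @export
simulate_breath <- function(cfg, event = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(event) && !inherits(event, "effort_event")) {
    stop("config error: event must be an effort_event or NULL", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt <- 1 / cfg$sample_rate
  t_tot <- 60 / cfg$rate
  ti <- t_tot / (1 + cfg$ie_ratio)
  te <- t_tot - ti
  tau <- te / 6
  label <- if (is.null(event)) "none" else event$target_label

  if (label == "dt") {
    out <- .simulate_dt(cfg, event, dt, ti, te, tau)
  } else {
    geo <- .archetype_geometry(cfg, event)
    vt <- cfg$tidal_volume
    ni <- max(2L, as.integer(round(ti / dt)))
    ne <- max(2L, as.integer(round(te / dt)))
    ti_eff <- (ni - 1) * dt
    v_in <- .insp_volume(cfg, (0:(ni - 1)) * dt, ti_eff, vt)
    v_ex <- geo$gap + (vt - geo$gap) * exp(-(1:ne) * dt / tau)
    p_in <- .interp_poly(geo$insp_vertices, v_in)
    p_ex <- .interp_poly(geo$exp_vertices, v_ex)
    v <- c(v_in, v_ex)
    p <- c(p_in, p_ex)
    out <- list(volume = v, pressure = p)
  }

  n <- length(out$volume)
  flow <- .flow_from_volume(out$volume, dt)
  pressure <- out$pressure + stats::rnorm(n, 0, cfg$noise_sd_pressure)
  flow_noisy <- flow + stats::rnorm(n, 0, cfg$noise_sd_flow)
  list(time = (0:(n - 1)) * dt, pressure = pressure, flow = flow_noisy,
       volume = out$volume, true_label = label, n = n)
}

# double triggering: two stacked ventilator cycles, exhalation of the first
# incomplete, merged into one breath whose inspiratory half has 5 segments
.simulate_dt <- function(cfg, event, dt, ti, te, tau) {
  vt <- cfg$tidal_volume
  a <- event$amplitude
  base <- .insp_base(cfg)
  f <- base$f
  v1 <- 0.444 * vt; dl <- 0.033 * vt; v2 <- 0.289 * vt
  v3 <- 0.667 * vt; vt2 <- 0.933 * vt
  q <- vt / ti
  p_n2 <- cfg$peep - 0.1 * a
  p_n3 <- cfg$peep - 0.5 * a
  phase <- function(n, v_from, v_to, p_from, p_to) {
    s <- seq_len(n) / n
    list(v = v_from + (v_to - v_from) * s, p = p_from + (p_to - p_from) * s)
  }
  n1 <- round(v1 / q / dt); n2 <- round(0.08 / dt); n3 <- round(0.35 / dt)
  n4 <- round((v3 - v2) / q / dt); n5 <- round((vt2 - v3) / q / dt)
  ph <- list(
    list(v = 0, p = f(0)),
    phase(n1, 0, v1, f(0), f(0) + cfg$e1 * v1),
    phase(n2, v1, v1 + dl, f(0) + cfg$e1 * v1, p_n2),
    phase(n3, v1 + dl, v2, p_n2, p_n3),
    phase(n4, v2, v3, p_n3, f(v3)),
    phase(n5, v3, vt2, f(v3), f(v3) + cfg$e2 * (vt2 - v3)))
  v <- unlist(lapply(ph, `[[`, "v"), use.names = FALSE)
  p <- unlist(lapply(ph, `[[`, "p"), use.names = FALSE)
  ptop2 <- p[length(p)]
  ne <- max(2L, as.integer(round(te / dt)))
  v_ex <- vt2 * exp(-(1:ne) * dt / tau)
  p_ex <- .interp_poly(.exp_base_vertices(cfg, vt2, ptop2), v_ex)
  list(volume = c(v, v_ex), pressure = c(p, p_ex))
}

#' Simulate a labelled sequence of breaths
#'
#' Concatenates `n_breaths` simulated breaths whose asynchrony types follow
#' the requested incidence mix (deterministic largest-remainder allocation,
#' order shuffled by `seed`), preceded by a short zero-flow lead-in. The
#' default mix assigns 7% of breaths to each of the seven types (49%
#' asynchronous in total), the package's standard evaluation cohort.
#'
#' @param cfg a [sim_config()].
#' @param mix named fractions over the seven type codes; entries >= 0 and
#'   summing to <= 1 (remainder = normal breaths).
#' @param n_breaths number of breaths, >= 1.
#' @param seed integer seed for the allocation shuffle and the noise draws.
#' @param amplitude effort amplitude passed to each [effort_event()].
#' @return list with `record` (a [waveform_record()]), `labels` (character,
#'   in breath order) and `events` (the per-breath effort events).
#' @export
simulate_sequence <- function(cfg, mix = NULL, n_breaths = 100, seed = 1,
                              amplitude = 4) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_breaths < 1) stop("config error: n_breaths must be >= 1", call. = FALSE)
  types <- asynchrony_types()
  if (is.null(mix)) mix <- stats::setNames(rep(0.07, 7), types)
  if (is.null(names(mix)) || !all(names(mix) %in% types)) {
    stop("config error: mix must be named with asynchrony type codes",
         call. = FALSE)
  }
  full <- stats::setNames(rep(0, 7), types)
  full[names(mix)] <- mix
  if (any(full < 0) || sum(full) > 1 + 1e-12) {
    stop("config error: mix fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  # largest-remainder allocation: counts within +/-1 of fraction * n
  raw <- full * n_breaths
  cnt <- floor(raw)
  left <- round(sum(raw)) - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  labels <- c(rep(names(cnt), cnt), rep("none", n_breaths - sum(cnt)))
  set.seed(seed)
  labels <- labels[sample.int(n_breaths)]

  dt <- 1 / cfg$sample_rate
  n_pad <- as.integer(round(0.3 * cfg$sample_rate))
  events <- vector("list", n_breaths)
  pieces_p <- vector("list", n_breaths + 1L)
  pieces_f <- vector("list", n_breaths + 1L)
  pieces_p[[1]] <- cfg$peep + stats::rnorm(n_pad, 0, cfg$noise_sd_pressure)
  pieces_f[[1]] <- stats::rnorm(n_pad, 0, cfg$noise_sd_flow)
  cfg_noseed <- cfg
  cfg_noseed$seed <- NULL
  for (b in seq_len(n_breaths)) {
    ev <- if (labels[b] == "none") NULL else
      effort_event(labels[b], amplitude = amplitude)
    events[[b]] <- ev
    br <- simulate_breath(cfg_noseed, ev)
    pieces_p[[b + 1L]] <- br$pressure
    pieces_f[[b + 1L]] <- br$flow
  }
  pressure <- unlist(pieces_p, use.names = FALSE)
  flow <- unlist(pieces_f, use.names = FALSE)
  time <- (seq_along(pressure) - 1) * dt
  list(record = waveform_record(time, pressure, flow),
       labels = labels, events = events)
}
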