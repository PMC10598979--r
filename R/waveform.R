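#' Construct and validate a ventilator waveform record
#'
#' A `waveform_record` holds uniformly sampled airway pressure and flow from a
#' mechanical ventilator. Units are fixed throughout the package: seconds,
#' cmH2O, L/s (positive flow = inspiratory); any conversion belongs at the
#' I/O boundary.
#'
#' @param time numeric vector of sample times (s), strictly increasing on a
#'   uniform grid (relative spacing tolerance 1e-6).
#' @param pressure airway pressure (cmH2O), same length as `time`.
#' @param flow airway flow (L/s), same length as `time`.
#' @param volume optional volume trace (L); when absent, downstream code
#'   integrates flow (see [integrate_volume()]).
#' @return an object of class `waveform_record` with fields `time`,
#'   `pressure`, `flow`, optionally `volume`, and `sample_rate` (Hz).
#' @export
waveform_record <- function(time, pressure, flow, volume = NULL) {
  n <- length(time)
  if (n < 2L) stop("data error: need at least 2 samples", call. = FALSE)
  if (length(pressure) != n || length(flow) != n) {
    stop("data error: time, pressure, flow must have identical length",
         call. = FALSE)
  }
  if (!is.null(volume) && length(volume) != n) {
    stop("data error: volume column length mismatch", call. = FALSE)
  }
  if (anyNA(time) || anyNA(pressure) || anyNA(flow)) {
    stop("data error: missing values in waveform", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("data error: time must be strictly increasing", call. = FALSE)
  }
  med <- stats::median(dt)
  if (any(abs(dt - med) > 1e-6 * med)) {
    stop("data error: non-uniform sampling (spacing varies beyond 1e-6 relative)",
         call. = FALSE)
  }
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 flow = as.numeric(flow), volume = volume,
                 sample_rate = 1 / med),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("waveform_record: %d samples at %.6g Hz (%.4g s)\n",
              length(x$time), x$sample_rate, diff(range(x$time))))
  cat(sprintf("  pressure %.4g..%.4g cmH2O, flow %.4g..%.4g L/s%s\n",
              min(x$pressure), max(x$pressure), min(x$flow), max(x$flow),
              if (is.null(x$volume)) "" else ", volume column present"))
  invisible(x)
}

#' Read a ventilator waveform from a delimited text file
#'
#' Expects a header row; the default column names follow the CSV dialect the
#' simulator writes (`time_s`, `paw_cmH2O`, `flow_Lps`, optional `vol_L`).
#'
#' @param path file path.
#' @param time_col,pressure_col,flow_col,volume_col column names; set
#'   `volume_col` to a present column to carry an exported volume trace
#'   instead of integrating flow.
#' @param delimiter field separator (default `","`).
#' @return a validated [waveform_record()].
#' @export
read_waveform <- function(path, time_col = "time_s", pressure_col = "paw_cmH2O",
                          flow_col = "flow_Lps", volume_col = "vol_L",
                          delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE)
  for (col in c(time_col, pressure_col, flow_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("format error: column '%s' not found in %s", col, path),
           call. = FALSE)
    }
  }
  vol <- if (!is.null(volume_col) && volume_col %in% names(df)) {
    as.numeric(df[[volume_col]])
  } else NULL
  waveform_record(df[[time_col]], df[[pressure_col]], df[[flow_col]], vol)
}

#' Write a waveform record as CSV
#'
#' Values are written with full (17 significant digit) precision so that a
#' write/read round trip reproduces them bit-identically.
#'
#' @param record a `waveform_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  df <- data.frame(time_s = record$time, paw_cmH2O = record$pressure,
                   flow_Lps = record$flow)
  if (!is.null(record$volume)) df$vol_L <- record$volume
  cols <- lapply(df, function(x) sprintf("%.17g", x))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Cumulative trapezoidal integration of flow to volume
#'
#' @param flow flow samples (L/s).
#' @param dt sample spacing (s), > 0.
#' @return volume samples (L); `volume[1] == 0`.
#' @examples
#' integrate_volume(rep(0.5, 101), 0.01)[101]  # 0.5 L after 1 s
#' @export
integrate_volume <- function(flow, dt) {
  if (!length(flow)) stop("data error: empty flow", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  c(0, cumsum((flow[-length(flow)] + flow[-1]) / 2 * dt))
}
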