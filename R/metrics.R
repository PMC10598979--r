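#' One-vs-rest confusion counts for an asynchrony label
#'
#' Tallies agreement between predicted and ground-truth labels for one target
#' type. With `target = "any"` all seven types collapse to a single
#' "asynchrony" class, giving the binary asynchrony-vs-none tally.
#'
#' @param pred,truth character vectors of equal length with values among the
#'   type codes and `"none"`.
#' @param target a type code or `"any"`.
#' @return object of class `confusion_counts`: list with `tp`, `fn`, `tn`,
#'   `fp`, `target`, `n`.
#' @export
confusion <- function(pred, truth, target = "any") {
  if (length(pred) != length(truth) || !length(pred)) {
    stop("data error: pred and truth must have equal length >= 1",
         call. = FALSE)
  }
  if (identical(target, "any")) {
    p <- pred != "none"
    t <- truth != "none"
  } else {
    target <- match.arg(target, asynchrony_types())
    p <- pred == target
    t <- truth == target
  }
  structure(list(tp = sum(p & t), fn = sum(!p & t),
                 tn = sum(!p & !t), fp = sum(p & !t),
                 target = target, n = length(pred)),
            class = "confusion_counts")
}

#' Build confusion counts from raw tallies
#' @param tp,fn,tn,fp non-negative counts.
#' @param target label the counts refer to.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, tn, fp, target = "any") {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp, target = target,
                 n = tp + fn + tn + fp),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts [%s]: TP %d  FN %d  TN %d  FP %d\n",
              x$target, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' Standard definitions: sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), accuracy = (TP + TN) / total. Undefined ratios (empty
#' denominator) return `NA`, the "not available" cell of a per-patient
#' summary with no positive (or no negative) breaths.
#'
#' @param c_ a [confusion_counts()] object.
#' @return fraction in \[0, 1\], or `NA` when undefined.
#' @export
sensitivity <- function(c_) {
  if (c_$tp + c_$fn == 0) return(NA_real_)
  c_$tp / (c_$tp + c_$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(c_) {
  if (c_$tn + c_$fp == 0) return(NA_real_)
  c_$tn / (c_$tn + c_$fp)
}

#' @rdname sensitivity
#' @export
accuracy <- function(c_) {
  tot <- c_$tp + c_$fn + c_$tn + c_$fp
  if (tot == 0) stop("data error: empty counts", call. = FALSE)
  (c_$tp + c_$tn) / tot
}

#' Format a fraction as a percentage at one decimal (half-up)
#' @param x fraction in \[0, 1\] (or `NA`).
#' @return character, e.g. `"89.5"`, or `"N/A"`.
#' @export
percent1 <- function(x) {
  ifelse(is.na(x), "N/A", sprintf("%.1f", floor(x * 1000 + 0.5) / 10))
}

#' Per-type evaluation table
#'
#' One-vs-rest confusion counts and metrics for each of the seven types,
#' the binary asynchrony-vs-none row, and the non-asynchrony row (counts of
#' the "none" class treated as the positive class).
#'
#' @param pred,truth label vectors.
#' @return data.frame with columns `target`, `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `accuracy` (raw fractions).
#' @export
evaluate_types <- function(pred, truth) {
  rows <- lapply(c(asynchrony_types(), "any"), function(tg) {
    cc <- confusion(pred, truth, tg)
    data.frame(target = tg, tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
               sensitivity = sensitivity(cc), specificity = specificity(cc),
               accuracy = accuracy(cc))
  })
  # non-asynchrony: the "none" class as positive
  cc <- confusion(ifelse(pred == "none", "fa", "none"),
                  ifelse(truth == "none", "fa", "none"), "fa")
  cc$target <- "non-asynchrony"
  rows[[length(rows) + 1L]] <-
    data.frame(target = "non-asynchrony", tp = cc$tp, fn = cc$fn, tn = cc$tn,
               fp = cc$fp, sensitivity = sensitivity(cc),
               specificity = specificity(cc), accuracy = accuracy(cc))
  do.call(rbind, rows)
}

#' Windowed incidence report
#'
#' The monitoring summary: per-window fractions of each type (windows of
#' `window_size` breaths, final partial window included and flagged),
#' cumulative per-breath running fractions, and the overall asynchrony
#' index (asynchronous breaths / total breaths).
#'
#' @param labels character vector of per-breath labels.
#' @param window_size breaths per window (default 100).
#' @return object of class `incidence_report`: list with `window_size`,
#'   `windows` (data.frame: window, start, end, partial, one fraction column
#'   per type and `none`), `cumulative` (matrix, breaths x types, running
#'   fractions), `asynchrony_index`.
#' @export
incidence_report <- function(labels, window_size = 100L) {
  n <- length(labels)
  if (!n) stop("labels must be non-empty", call. = FALSE)
  if (window_size < 1L) stop("window_size must be >= 1", call. = FALSE)
  lev <- c(asynchrony_types(), "none")
  starts <- seq(1L, n, by = window_size)
  windows <- do.call(rbind, lapply(seq_along(starts), function(w) {
    idx <- starts[w]:min(starts[w] + window_size - 1L, n)
    tab <- table(factor(labels[idx], levels = lev)) / length(idx)
    cbind(data.frame(window = w, start = idx[1], end = idx[length(idx)],
                     partial = length(idx) < window_size),
          as.data.frame(as.list(tab)))
  }))
  ind <- vapply(lev, function(l) cumsum(labels == l), numeric(n))
  cumulative <- ind / seq_len(n)
  structure(list(window_size = as.integer(window_size), windows = windows,
                 cumulative = cumulative,
                 asynchrony_index = mean(labels != "none")),
            class = "incidence_report")
}

#' @export
print.incidence_report <- function(x, ...) {
  cat(sprintf("incidence_report: %d windows of %d breaths, asynchrony index %.3f\n",
              nrow(x$windows), x$window_size, x$asynchrony_index))
  print(x$windows[, c("window", "start", "end", "partial",
                      asynchrony_types(), "none")], row.names = FALSE)
  invisible(x)
}
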