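# S3 containers shared by all pipeline stages.
#
# A trace matrix stores frames in rows and cells in columns (the natural R
# layout for per-cell column operations); `time_s` is the shared clock.

#' Construct a raw fluorescence trace matrix
#'
#' The central table of the pipeline: time-aligned raw fluorescence for every
#' cell of one macula densa plaque, in arbitrary units (AU).
#'
#' @param time_s Numeric vector of sample times in seconds; strictly
#'   increasing and uniformly spaced at `1/fs_hz`.
#' @param values Numeric matrix, frames x cells, raw fluorescence (AU);
#'   must be non-negative.
#' @param fs_hz Sampling rate in Hz.
#' @param cell_ids Unique cell labels; defaults to `cell_001`, `cell_002`, ...
#' @param labels Optional per-cell class/condition labels (named or in cell
#'   order).
#' @return A `trace_matrix` object.
#' @export
trace_matrix <- function(values, fs_hz, time_s = NULL, cell_ids = NULL,
                         labels = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stopf("fs_hz must be a positive scalar")
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / fs_hz
  if (length(time_s) != n) stopf("time_s length != number of frames")
  dt <- diff(time_s)
  if (n > 1 && (any(dt <= 0) ||
                max(abs(dt - 1 / fs_hz)) > 1e-6 / fs_hz))
    stopf("time_s must be strictly increasing and uniform at 1/fs_hz")
  if (any(values < 0)) stopf("negative fluorescence values")
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values) %||% sprintf("cell_%03d", seq_len(ncol(values)))
  }
  if (anyDuplicated(cell_ids)) stopf("cell_ids must be unique")
  colnames(values) <- cell_ids
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[cell_ids]
    if (length(labels) != length(cell_ids))
      stopf("labels length must match number of cells")
    labels <- stats::setNames(as.character(labels), cell_ids)
  }
  structure(
    list(time_s = as.numeric(time_s), values = values, fs_hz = fs_hz,
         cell_ids = cell_ids, labels = labels),
    class = "trace_matrix"
  )
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d frames @ %.3g Hz (%.1f s)\n",
              length(x$cell_ids), nrow(x$values), x$fs_hz,
              nrow(x$values) / x$fs_hz))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Construct a baseline-normalized (F/F0) trace matrix
#'
#' @param trace A [trace_matrix()] whose values are already F/F0
#'   (dimensionless).
#' @param f0 Per-cell baseline estimate in AU (vector, or frames x cells
#'   matrix for rolling baselines); all entries must be positive.
#' @param method Character descriptor of the baseline estimator.
#' @return A `normalized_trace_matrix` (also a `trace_matrix`).
#' @export
normalized_trace_matrix <- function(trace, f0, method) {
  stopifnot(inherits(trace, "trace_matrix"))
  if (any(f0 <= 0)) stopf("baseline f0 must be positive")
  trace$f0 <- f0
  trace$method <- method
  class(trace) <- c("normalized_trace_matrix", "trace_matrix")
  trace
}

#' @export
print.normalized_trace_matrix <- function(x, ...) {
  cat(sprintf("<normalized_trace_matrix> %d cells x %d frames @ %.3g Hz (F/F0, baseline: %s)\n",
              length(x$cell_ids), nrow(x$values), x$fs_hz, x$method))
  invisible(x)
}

#' Construct an arteriole-diameter (vasomotion) trace
#'
#' @param time_s Sample times in seconds (same convention as
#'   [trace_matrix()]).
#' @param diameter Arteriole diameter per sample (micrometres or AU).
#' @param fs_hz Sampling rate in Hz.
#' @return A `vasomotion_trace` object.
#' @export
vasomotion_trace <- function(time_s, diameter, fs_hz) {
  if (length(time_s) != length(diameter))
    stopf("time_s and diameter lengths differ")
  structure(list(time_s = as.numeric(time_s),
                 diameter = as.numeric(diameter), fs_hz = fs_hz),
            class = "vasomotion_trace")
}

#' @export
print.vasomotion_trace <- function(x, ...) {
  cat(sprintf("<vasomotion_trace> %d samples @ %.3g Hz, mean diameter %.2f\n",
              length(x$diameter), x$fs_hz, mean(x$diameter)))
  invisible(x)
}
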