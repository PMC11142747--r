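# Trace extraction and F/F0 preprocessing.

#' Extract per-cell mean-intensity traces from an image stack
#'
#' The ROI statistic is the mean pixel intensity over each cell's labelled
#' mask region — robust to ROI size differences between cells. Cells are
#' returned in ascending label order.
#'
#' @param stack Numeric array, frames x rows x cols.
#' @param mask Integer matrix (rows x cols) of ROI labels; 0 = background.
#' @param fs_hz Sampling rate in Hz.
#' @param stat ROI reduction, `"mean"` (default) or `"sum"`.
#' @return A [trace_matrix()] with one column per nonzero label.
#' @export
extract_roi_traces <- function(stack, mask, fs_hz, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  d <- dim(stack)
  if (length(d) != 3) stopf("stack must be a frames x rows x cols array")
  if (!all(dim(mask) == d[2:3])) stopf("mask shape must match frame shape")
  labels <- sort(unique(as.integer(mask[mask > 0])))
  if (!length(labels)) stopf("mask contains no nonzero labels")
  n_frames <- d[1]
  flat <- matrix(stack, n_frames, d[2] * d[3])
  values <- matrix(0, n_frames, length(labels))
  for (j in seq_along(labels)) {
    px <- which(as.vector(mask) == labels[j])
    if (!length(px)) stopf("label %d has zero pixels", labels[j])
    values[, j] <- if (stat == "mean") rowMeans(flat[, px, drop = FALSE])
                   else rowSums(flat[, px, drop = FALSE])
  }
  trace_matrix(pmax(values, 0), fs_hz,
               cell_ids = sprintf("cell_%03d", labels))
}

#' Maximum (or sum) projection of an image stack
#'
#' The time-lapse maximum-projection image highlights cells by their peak
#' fluorescence over the recording.
#'
#' @param stack Numeric array, frames x rows x cols, with at least 1 frame.
#' @param mode `"max"` (pixelwise maximum) or `"sum"`.
#' @return rows x cols matrix.
#' @export
max_projection <- function(stack, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  d <- dim(stack)
  if (length(d) != 3 || d[1] < 1) stopf("stack must have at least one frame")
  flat <- matrix(stack, d[1], d[2] * d[3])
  proj <- if (mode == "max") apply(flat, 2, max) else colSums(flat)
  matrix(proj, d[2], d[3])
}

# Windowed "mean of samples <= q-th percentile" statistic.
lower_percentile_mean <- function(x, q) {
  thr <- stats::quantile(x, q / 100, names = FALSE)
  sel <- x[x <= thr]
  if (!length(sel)) return(mean(x))  # degenerate; caller logs
  mean(sel)
}

#' Estimate per-cell baseline fluorescence F0
#'
#' `"percentile"` (default): F0 is the mean of all samples at or below the
#' q-th percentile of the full trace — appropriate for pacemaker-like
#' activity where the ~2 s spike / ~33 s period duty cycle leaves >90% of
#' samples at baseline. `"rolling_percentile"`: the same statistic in a
#' centred sliding window (edges padded by reflection), for drifting
#' baselines; returns a frames x cells matrix.
#'
#' @param trace A [trace_matrix()].
#' @param method `"percentile"` or `"rolling_percentile"`.
#' @param q Percentile in (0, 50].
#' @param window_s Rolling window length in seconds (>= 10 samples).
#' @return Named per-cell vector (percentile) or frames x cells matrix
#'   (rolling).
#' @export
estimate_baseline <- function(trace,
                              method = c("percentile", "rolling_percentile"),
                              q = 20, window_s = 60) {
  stopifnot(inherits(trace, "trace_matrix"))
  method <- match.arg(method)
  if (q <= 0 || q > 50) stopf("q must lie in (0, 50]")
  v <- trace$values
  if (method == "percentile") {
    f0 <- apply(v, 2, function(x) {
      if (all(x == x[1])) {
        log_warn("baseline", "constant trace; baseline set to its value")
        return(x[1])
      }
      lower_percentile_mean(x, q)
    })
    return(stats::setNames(f0, trace$cell_ids))
  }
  w <- round(window_s * trace$fs_hz)
  if (w < 10) stopf("rolling window must span >= 10 samples")
  half <- w %/% 2
  n <- nrow(v)
  out <- matrix(0, n, ncol(v), dimnames = list(NULL, trace$cell_ids))
  for (j in seq_len(ncol(v))) {
    xp <- pad_reflect(v[, j], half)
    out[, j] <- vapply(seq_len(n), function(k)
      lower_percentile_mean(xp[k:(k + 2 * half)], q), numeric(1))
  }
  out
}

#' Normalize fluorescence to baseline (F/F0)
#'
#' @param trace A [trace_matrix()] of raw fluorescence.
#' @param baseline Per-cell F0 (vector or frames x cells matrix), all
#'   entries positive; defaults to [estimate_baseline()] with the global
#'   20th-percentile method.
#' @return A [normalized_trace_matrix()].
#' @export
normalize_traces <- function(trace, baseline = NULL) {
  stopifnot(inherits(trace, "trace_matrix"))
  method <- "user-supplied"
  if (is.null(baseline)) {
    baseline <- estimate_baseline(trace)
    method <- "percentile(q=20)"
  }
  if (any(baseline <= 0)) stopf("baseline must be positive")
  v <- trace$values
  if (is.matrix(baseline)) {
    if (!all(dim(baseline) == dim(v)))
      stopf("matrix baseline must match trace dimensions")
    trace$values <- v / baseline
    if (method == "user-supplied") method <- "rolling"
  } else {
    if (length(baseline) != ncol(v))
      stopf("baseline length must equal number of cells")
    trace$values <- sweep(v, 2, baseline, "/")
  }
  normalized_trace_matrix(trace, baseline, method)
}

# Savitzky-Golay coefficients for smoothing (derivative 0): first row of the
# least-squares polynomial projection matrix.
savgol_coef <- function(half, poly) {
  x <- -half:half
  A <- outer(x, 0:poly, `^`)
  (A %*% solve(crossprod(A), t(A)))[half + 1, ]
}

smooth_vector <- function(x, w, method, poly = 3) {
  half <- w %/% 2
  xp <- pad_reflect(x, half)
  kern <- if (method == "moving_average") rep(1 / w, w)
          else savgol_coef(half, min(poly, w - 2))
  out <- stats::filter(xp, kern, sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

#' Smooth traces
#'
#' Length-preserving low-pass filtering with reflective edge handling. The
#' window is rounded to an odd number of samples.
#'
#' @param trace A [trace_matrix()] (or plain numeric vector).
#' @param method `"moving_average"` (default) or `"savitzky_golay"`
#'   (order-3 polynomial).
#' @param window_s Window length in seconds; must span >= 3 samples and not
#'   exceed the trace.
#' @param fs_hz Sampling rate, required when `trace` is a bare vector.
#' @return Same type as the input, smoothed.
#' @export
smooth_traces <- function(trace,
                          method = c("moving_average", "savitzky_golay"),
                          window_s = 1, fs_hz = NULL) {
  method <- match.arg(method)
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(fs_hz)) stopf("fs_hz required for a bare vector")
    w <- smooth_window_samples(window_s, fs_hz, length(trace))
    return(smooth_vector(trace, w, method))
  }
  stopifnot(inherits(trace, "trace_matrix"))
  w <- smooth_window_samples(window_s, trace$fs_hz, nrow(trace$values))
  trace$values <- apply(trace$values, 2, smooth_vector, w = w,
                        method = method)
  trace
}

smooth_window_samples <- function(window_s, fs_hz, n) {
  w <- round(window_s * fs_hz)
  if (w %% 2 == 0) w <- w + 1
  if (w < 3) stopf("window_s must span at least 3 samples")
  if (w > n) stopf("smoothing window (%d samples) longer than trace (%d)",
                   w, n)
  w
}
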