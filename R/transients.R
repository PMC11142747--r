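# Ca2+ transient detection and per-cell physiology metrics.
#
# Detection is noise-referenced: candidate peaks on the smoothed (F/F0 - 1)
# signal must exceed k_mad robust-SD units of the sub-threshold residual
# (MAD estimate iterated twice so spikes cannot inflate the noise scale),
# carry a minimum topographic prominence, and respect a minimum peak-to-peak
# separation (the higher peak wins; ties go to the earlier one).

# Local maxima indices (strictly greater than the left neighbour, >= right,
# so plateaus yield their first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# Topographic prominence of each peak: height above the higher of the two
# minima separating it from the nearest higher ground (or signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- 1; right <- length(x)
    hi_l <- which(x[1:(p - 1)] > h)
    if (length(hi_l)) left <- max(hi_l)
    hi_r <- which(x[(p + 1):length(x)] > h)
    if (length(hi_r)) right <- p + min(hi_r)
    base_l <- min(x[left:p])
    base_r <- min(x[p:right])
    h - max(base_l, base_r)
  }, numeric(1))
}

# Iterated MAD noise threshold on y (signal with baseline ~ 0).
noise_threshold <- function(y, k_mad, iterations = 2) {
  thr <- Inf
  center <- 0; sigma <- 0
  for (it in seq_len(iterations)) {
    sub <- y[y < thr]
    if (length(sub) < 5) break
    center <- stats::median(sub)
    sigma <- stats::mad(sub, center = center)  # 1.4826 * MAD
    thr <- center + k_mad * sigma
  }
  list(threshold = center + k_mad * sigma, center = center, sigma = sigma)
}

#' Detect Ca2+ transients on normalized traces
#'
#' @param norm A [normalized_trace_matrix()] (values are F/F0). A baseline
#'   far from 1 triggers a warning — raw traces should be normalized first.
#' @param k_mad Threshold in robust noise SD units (default 3).
#' @param min_interval_s Minimum peak-to-peak separation in seconds
#'   (default 2); of two closer peaks the higher is kept.
#' @param min_prominence Minimum peak prominence on the F/F0 scale
#'   (default 0.5).
#' @param smooth_window_s Pre-detection smoothing window (s); peak
#'   amplitude/FWHM are still measured on the unsmoothed trace.
#' @return `data.frame` with one row per event: `cell_id`, `onset_s`,
#'   `peak_s`, `peak_ffo`, `fwhm_s`, `auc`, `edge_truncated`.
#' @export
detect_transients <- function(norm, k_mad = 3, min_interval_s = 2,
                              min_prominence = 0.5, smooth_window_s = 1) {
  stopifnot(inherits(norm, "trace_matrix"))
  v <- norm$values
  if (nrow(v) < 10) stopf("trace must have >= 10 samples")
  med_all <- stats::median(v)
  # catches raw-AU input (median ~ baseline_au); a high-duty-cycle plaque
  # legitimately has median F/F0 up to a few-fold
  if (med_all > 5 || med_all < 0.2)
    log_warn("transients", sprintf(
      "input median %.3g far from 1: is this F/F0?", med_all))
  fs <- norm$fs_hz
  out <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    out[[j]] <- detect_transients_one(v[, j], fs, norm$time_s,
                                      norm$cell_ids[j], k_mad,
                                      min_interval_s, min_prominence,
                                      smooth_window_s)
  }
  do.call(rbind, out)
}

detect_transients_one <- function(x, fs, time_s, cell_id, k_mad,
                                  min_interval_s, min_prominence,
                                  smooth_window_s) {
  empty <- data.frame(cell_id = character(0), onset_s = numeric(0),
                      peak_s = numeric(0), peak_ffo = numeric(0),
                      fwhm_s = numeric(0), auc = numeric(0),
                      edge_truncated = logical(0))
  y <- smooth_vector(x,
                     smooth_window_samples(smooth_window_s, fs, length(x)),
                     "moving_average") - 1
  nt <- noise_threshold(y, k_mad)
  peaks <- local_maxima(y)
  peaks <- peaks[y[peaks] > nt$threshold]
  if (!length(peaks)) return(empty)
  prom <- peak_prominence(y, peaks)
  peaks <- peaks[prom >= min_prominence]
  if (!length(peaks)) return(empty)

  # greedy separation: higher peak wins, ties to the earlier one
  ord <- order(-y[peaks], peaks)
  keep <- logical(length(peaks))
  min_sep <- min_interval_s * fs
  for (k in ord) {
    if (!any(abs(peaks[keep] - peaks[k]) < min_sep)) keep[k] <- TRUE
  }
  peaks <- sort(peaks[keep])

  # refine each peak to the unsmoothed local maximum; the window is limited
  # to the smoother's half-support — refinement only undoes the peak
  # displacement smoothing can cause, a wider window would turn peak_ffo
  # into an upward-biased max-of-noise estimate
  half <- max(1L, smooth_window_samples(smooth_window_s, fs,
                                        length(x)) %/% 2L)
  n <- length(x)
  ref <- vapply(peaks, function(p) {
    idx <- max(1, p - half):min(n, p + half)
    idx[which.max(x[idx])]
  }, integer(1))

  # per-event bounds: midpoints between adjacent peaks (half-open windows)
  bounds_l <- c(1L, ceiling((ref[-length(ref)] + ref[-1]) / 2))
  bounds_r <- c(bounds_l[-1] - 1L, n)

  onset <- integer(length(ref))
  for (k in seq_along(ref)) {
    below <- which(y[bounds_l[k]:ref[k]] <= nt$threshold)
    onset[k] <- if (length(below)) bounds_l[k] + max(below) - 1L
                else bounds_l[k]
  }
  fwhm <- vapply(seq_along(ref), function(k)
    fwhm_one(x, fs, ref[k], onset[k], bounds_l[k], bounds_r[k]),
    numeric(1))
  auc <- vapply(seq_along(ref), function(k) {
    idx <- bounds_l[k]:bounds_r[k]
    trapz(time_s[idx], pmax(x[idx] - 1, 0))
  }, numeric(1))
  edge <- ref - fs * min_interval_s < 1 | ref + fs * min_interval_s > n

  data.frame(cell_id = cell_id, onset_s = time_s[onset],
             peak_s = time_s[ref], peak_ffo = x[ref], fwhm_s = fwhm,
             auc = auc, edge_truncated = edge)
}

# FWHM about a local baseline (median of the 5 s preceding onset), crossing
# times by linear interpolation; NA when the half level is never crossed
# within the event bounds.
fwhm_one <- function(x, fs, peak, onset, lo, hi) {
  pre <- max(1, onset - round(5 * fs)):max(1, onset - 1)
  base <- if (onset > 1) stats::median(x[pre]) else stats::median(x[lo:hi])
  half <- base + (x[peak] - base) / 2
  # left crossing
  li <- NA_real_
  for (i in peak:lo) {
    if (x[i] <= half && i < length(x)) {
      li <- i + (half - x[i]) / (x[i + 1] - x[i])
      break
    }
  }
  ri <- NA_real_
  if (peak < hi) for (i in peak:hi) {
    if (x[i] <= half) {
      ri <- i - (half - x[i]) / (x[i - 1] - x[i])
      break
    }
  }
  if (is.na(li) || is.na(ri)) return(NA_real_)
  (ri - li) / fs
}

#' Measure the FWHM of one detected event
#'
#' Width at half of (peak F/F0 - local baseline) above the local baseline,
#' with crossing times linearly interpolated between samples. The local
#' baseline is the median of the 5 s preceding the event onset, so slowly
#' drifting plateaus measure correctly.
#'
#' @param event One-row data.frame from [detect_transients()] (or a list
#'   with `peak_s` and `onset_s`).
#' @param norm The [normalized_trace_matrix()] the event was detected on.
#' @param cell_id Cell to measure (defaults to `event$cell_id`).
#' @return FWHM in seconds, or `NA` if the half level is never crossed.
#' @export
event_fwhm <- function(event, norm, cell_id = NULL) {
  stopifnot(inherits(norm, "trace_matrix"))
  cell_id <- cell_id %||% event$cell_id
  x <- norm$values[, as.character(cell_id)]
  fs <- norm$fs_hz
  peak <- round(event$peak_s * fs) + 1L
  if (peak < 1 || peak > length(x)) stopf("event peak outside trace")
  onset <- max(1L, round(event$onset_s * fs) + 1L)
  fwhm_one(x, fs, peak, onset, 1L, length(x))
}

#' Per-cell physiology metrics
#'
#' Summarizes detected events per cell over an analysis window: firing
#' frequency (events/s, exactly count/duration), mean FWHM and mean peak
#' F/F0 over non-truncated events, number of events, and cumulative
#' activity — the trapezoidal integral of max(F/F0 - 1, 0) over the window
#' (the "cumulative Ca2+ elevation" used for cross-cell-type comparison).
#'
#' @param events Event table from [detect_transients()].
#' @param norm The [normalized_trace_matrix()].
#' @param window `c(t0, t1)` half-open analysis window in seconds; default
#'   the full recording.
#' @return `data.frame` with one row per cell (all cells in `norm`,
#'   including event-free ones).
#' @export
cell_metrics <- function(events, norm, window = NULL) {
  stopifnot(inherits(norm, "trace_matrix"))
  t_all <- norm$time_s
  if (is.null(window)) window <- c(t_all[1], t_all[length(t_all)] +
                                     1 / norm$fs_hz)
  dur <- window[2] - window[1]
  if (dur <= 0) stopf("empty analysis window")
  in_win <- t_all >= window[1] & t_all < window[2]
  if (!any(in_win)) stopf("window outside recording")

  res <- lapply(seq_along(norm$cell_ids), function(j) {
    id <- norm$cell_ids[j]
    ev <- events[events$cell_id == id &
                   events$peak_s >= window[1] & events$peak_s < window[2], ,
                 drop = FALSE]
    full <- ev[!ev$edge_truncated, , drop = FALSE]
    x <- norm$values[in_win, j]
    data.frame(
      cell_id = id,
      n_events = nrow(ev),
      frequency_hz = nrow(ev) / dur,
      mean_fwhm_s = if (nrow(full)) mean(full$fwhm_s, na.rm = TRUE)
                    else NA_real_,
      mean_peak_fold = if (nrow(full)) mean(full$peak_ffo) else NA_real_,
      cumulative_activity = trapz(t_all[in_win], pmax(x - 1, 0)),
      label = if (!is.null(norm$labels)) norm$labels[[id]] else NA_character_
    )
  })
  do.call(rbind, res)
}

#' Response of one cell to a timed stimulus
#'
#' Compares half-open pre `[t_stim - pre, t_stim)` and post
#' `[t_stim, t_stim + post)` windows: `delta_steady_state` is the relative
#' change in mean F/F0, `delta_frequency_hz` the change in firing frequency.
#'
#' @param norm A [normalized_trace_matrix()].
#' @param events Event table from [detect_transients()].
#' @param t_stim_s Stimulus time (s); must lie inside the recording.
#' @param pre_window_s,post_window_s Window lengths (s); default 120 s
#'   baseline before the stimulus.
#' @param cell_id Cell to analyse (default: first cell).
#' @return One-row `data.frame` with the two deltas and the window means.
#' @export
stimulus_response <- function(norm, events, t_stim_s, pre_window_s = 120,
                              post_window_s = 120, cell_id = NULL) {
  stopifnot(inherits(norm, "trace_matrix"))
  t_all <- norm$time_s
  t_end <- t_all[length(t_all)] + 1 / norm$fs_hz
  if (t_stim_s <= t_all[1] || t_stim_s >= t_end)
    stopf("t_stim_s outside recording")
  pre_window_s <- min(pre_window_s, t_stim_s - t_all[1])
  post_window_s <- min(post_window_s, t_end - t_stim_s)
  cell_id <- cell_id %||% norm$cell_ids[1]
  x <- norm$values[, as.character(cell_id)]
  pre_idx <- t_all >= t_stim_s - pre_window_s & t_all < t_stim_s
  post_idx <- t_all >= t_stim_s & t_all < t_stim_s + post_window_s
  ev <- events[events$cell_id == cell_id, , drop = FALSE]
  pre_n <- sum(ev$peak_s >= t_stim_s - pre_window_s & ev$peak_s < t_stim_s)
  post_n <- sum(ev$peak_s >= t_stim_s &
                  ev$peak_s < t_stim_s + post_window_s)
  pre_mean <- mean(x[pre_idx])
  data.frame(cell_id = cell_id, t_stim_s = t_stim_s,
             pre_mean_ffo = pre_mean, post_mean_ffo = mean(x[post_idx]),
             delta_steady_state = (mean(x[post_idx]) - pre_mean) / pre_mean,
             pre_frequency_hz = pre_n / pre_window_s,
             post_frequency_hz = post_n / post_window_s,
             delta_frequency_hz = post_n / post_window_s -
               pre_n / pre_window_s)
}
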