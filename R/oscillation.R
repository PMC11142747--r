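# Whole-plaque oscillation metrics and Ca2+-vasomotion coupling.

#' Whole-plaque mean F/F0 signal
#'
#' Unweighted mean of F/F0 across the included cells at each frame — the
#' "whole-MD" readout that clusters single-cell transients into the plaque
#' rhythm.
#'
#' @param norm A [normalized_trace_matrix()].
#' @param cells Optional subset of cell ids (default: all).
#' @return A `whole_md_signal`: list with `time_s`, `value`, `fs_hz`,
#'   `n_cells`.
#' @export
whole_md_signal <- function(norm, cells = NULL) {
  stopifnot(inherits(norm, "trace_matrix"))
  cells <- cells %||% norm$cell_ids
  if (!length(cells)) stopf("empty cell subset")
  missing <- setdiff(cells, norm$cell_ids)
  if (length(missing)) stopf("unknown cell(s): %s",
                             paste(missing, collapse = ", "))
  structure(list(time_s = norm$time_s,
                 value = rowMeans(norm$values[, cells, drop = FALSE]),
                 fs_hz = norm$fs_hz, n_cells = length(cells)),
            class = "whole_md_signal")
}

#' @export
print.whole_md_signal <- function(x, ...) {
  cat(sprintf("<whole_md_signal> mean of %d cells, %d frames @ %g Hz\n",
              x$n_cells, length(x$value), x$fs_hz))
  invisible(x)
}

# Welch power spectral density: Hann-windowed segments, 50% overlap.
welch_psd <- function(x, fs, segment_s) {
  n <- length(x)
  L <- min(n, max(16, round(segment_s * fs)))
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  acc <- numeric(floor(L / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / (length(starts) * sum(w^2) * fs)
  freq <- (seq_along(acc) - 1) * fs / L
  list(freq = freq, psd = psd)
}

#' Oscillation regularity metrics of the whole-plaque signal
#'
#' Peaks are found with the transient detector applied to the plaque
#' signal. Regular pacemaker-like activity gives a low inter-peak-interval
#' CV and a low spectral entropy; irregular chaotic-like activity (as in
#' the NGFR-knockout) raises both. The dominant frequency is the arg-max of
#' the Welch periodogram over (0, fs/2], with segments spanning at least
#' four expected oscillation periods.
#'
#' @param signal A [whole_md_signal()] (>= 60 s).
#' @param expected_period_s Expected oscillation period, sets the Welch
#'   segment length (default 33.33 s, the tubuloglomerular-feedback
#'   rhythm).
#' @param k_mad,min_interval_s,min_prominence Peak-detection parameters,
#'   see [detect_transients()]. The prominence default matches the
#'   single-cell detector: in an n-cell plaque mean one solitary transient
#'   contributes only amplitude/n (~0.12 for 25 cells), so 0.5 admits
#'   drive-locked cluster peaks while rejecting single-cell bumps.
#' @return An `oscillation_metrics` list: `dominant_frequency_hz`,
#'   `isi_cv` (`NA` with < 3 peaks), `spectral_entropy` in [0, 1],
#'   `n_peaks`, `peak_times_s`.
#' @export
oscillation_metrics <- function(signal, expected_period_s = 100 / 3,
                                k_mad = 3, min_interval_s = 2,
                                min_prominence = 0.5) {
  stopifnot(inherits(signal, "whole_md_signal"))
  n <- length(signal$value)
  fs <- signal$fs_hz
  if (n / fs < 60) stopf("need >= 60 s of signal")

  as_norm <- trace_matrix(matrix(signal$value, ncol = 1,
                                 dimnames = list(NULL, "whole_md")),
                          fs, signal$time_s)
  as_norm <- normalized_trace_matrix(as_norm, 1, "whole-plaque mean")
  ev <- detect_transients(as_norm, k_mad = k_mad,
                          min_interval_s = min_interval_s,
                          min_prominence = min_prominence)
  peaks <- sort(ev$peak_s)
  isi_cv <- if (length(peaks) >= 3) {
    isi <- diff(peaks)
    stats::sd(isi) / mean(isi)
  } else NA_real_

  sp <- welch_psd(signal$value, fs, 4 * expected_period_s)
  pos <- sp$freq > 0
  psd <- sp$psd[pos]
  dominant <- sp$freq[pos][which.max(psd)]
  p <- psd / sum(psd)
  p <- p[p > 0]
  entropy <- -sum(p * log(p)) / log(sum(pos))

  structure(list(dominant_frequency_hz = dominant, isi_cv = isi_cv,
                 spectral_entropy = entropy, n_peaks = length(peaks),
                 peak_times_s = peaks),
            class = "oscillation_metrics")
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat(sprintf(
    "<oscillation_metrics> dominant %.4f Hz, %d peaks, ISI CV %s, spectral entropy %.3f\n",
    x$dominant_frequency_hz, x$n_peaks,
    ifelse(is.na(x$isi_cv), "NA", sprintf("%.3f", x$isi_cv)),
    x$spectral_entropy))
  invisible(x)
}

#' Cross-correlation coupling between plaque Ca2+ and arteriole diameter
#'
#' Both series are mean-removed and variance-normalized; the lag is the
#' arg-max of the normalized cross-correlation over integer-sample lags in
#' `[-max_lag_s, +max_lag_s]` (ties resolved to the smallest |lag|).
#' Positive lag means Ca2+ leads the diameter signal. A diameter series on
#' a different time base is linearly resampled onto the Ca2+ clock.
#'
#' @param signal A [whole_md_signal()] (or any list with `time_s`, `value`,
#'   `fs_hz`).
#' @param diameter A [vasomotion_trace()].
#' @param max_lag_s Search bound in seconds; must be < duration / 4.
#' @return A `coupling_result`: `lag_s`, `max_xcorr`, plus the full
#'   `lags_s` / `xcorr` profile.
#' @export
vasomotion_coupling <- function(signal, diameter, max_lag_s = 15) {
  x <- signal$value
  t_x <- signal$time_s
  fs <- signal$fs_hz
  y <- diameter$diameter
  if (!isTRUE(all.equal(diameter$time_s, t_x, tolerance = 1e-9)))
    y <- stats::approx(diameter$time_s, y, xout = t_x, rule = 2)$y
  n <- length(x)
  if (max_lag_s >= (n / fs) / 4) stopf("max_lag_s must be < duration / 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero-variance input to coupling")
  x <- (x - mean(x)) / stats::sd(x)
  y <- (y - mean(y)) / stats::sd(y)
  max_lag <- round(max_lag_s * fs)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- x[1:(n - l)]; ys <- y[(1 + l):n]
    } else {
      xs <- x[(1 - l):n]; ys <- y[1:(n + l)]
    }
    sum(xs * ys) / (n - 1)
  }, numeric(1))
  best <- order(-r, abs(lags), -lags)[1]
  structure(list(lag_s = lags[best] / fs, max_xcorr = r[best],
                 lags_s = lags / fs, xcorr = r),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> lag %.3f s (Ca2+ leads if > 0), r = %.3f\n",
              x$lag_s, x$max_xcorr))
  invisible(x)
}
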