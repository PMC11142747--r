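# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Raw trace with Gaussian spikes at known centers (seconds).
spike_trace <- function(centers, duration_s = 100, fs = 4, sigma = 0.85,
                        amp_fold = 3, baseline = 100, noise_sd = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- rep(1, length(t))
  for (cc in centers) x <- x + amp_fold * exp(-(t - cc)^2 / (2 * sigma^2))
  v <- baseline * x
  if (noise_sd > 0) v <- v + rnorm(length(t), 0, noise_sd)
  trace_matrix(matrix(pmax(v, 1e-9), ncol = 1,
                      dimnames = list(NULL, "cell_001")),
               fs, t)
}

as_norm <- function(trace) normalize_traces(trace)

# Single-cell uncoupled config (pure Gamma renewal firing).
solo_config <- function(seed, shape = 25, scale = 4 / 3, noise = 0.02,
                        duration_s = 600, ...) {
  plaque_config(n_cells = 1, class_counts = c(pacemaker = 1),
                coupling_by_class = list(pacemaker = 0),
                isi_gamma_shape = shape, isi_gamma_scale_s = scale,
                noise_sd_frac = noise, baseline_cell_sd = 0, seed = seed,
                duration_s = duration_s, ...)
}

# Direct two-pass Pearson correlation (independent oracle for the
# connectome module).
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

expect_silent_file <- function(path) {
  expect_true(file.exists(path), label = paste(path, "exists"))
}
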