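# Synthetic macula densa plaque simulator.
#
# Generative model: a latent pacemaker drive (jittered impulse train at the
# tubuloglomerular-feedback period, smoothed by the spike kernel) paces the
# plaque. Each cell fires a renewal spike train with Gamma inter-spike
# intervals; each spike is independently snapped to the nearest drive peak
# with probability equal to the cell's coupling coefficient. Spikes are
# phenomenological Gaussian bumps added on the fractional scale before
# multiplying the per-cell baseline; vasomotion follows the smoothed drive.

MD_CLASSES <- c("pacemaker", "follower_high", "follower_med",
                "follower_low", "lone")

#' Simulation parameters for one macula densa plaque
#'
#' Defaults describe a wild-type plaque: ~25 cells, ~0.03 Hz pacemaker
#' rhythm (drive period 33.33 s), Gaussian spikes of sigma 0.85 s (FWHM
#' ~2 s) reaching 4-fold baseline at the peak.
#'
#' @param n_cells Number of cells; must equal `sum(class_counts)`.
#' @param duration_s Recording length in seconds.
#' @param fs_hz Sampling rate (Hz); `fs_hz * duration_s` must be a positive
#'   integer frame count.
#' @param class_counts Named integer vector of cells per class.
#' @param drive_period_s Latent drive period in seconds.
#' @param drive_phase_jitter_sd_s SD of the Gaussian jitter on each drive
#'   peak time (s).
#' @param isi_gamma_shape,isi_gamma_scale_s Gamma inter-spike-interval
#'   parameters of the uncoupled renewal process (mean = shape * scale).
#' @param spike_sigma_s Gaussian spike kernel width sigma (s); FWHM =
#'   2.3548 * sigma.
#' @param spike_amplitude_fold Added spike amplitude relative to baseline
#'   (peak F/F0 of an isolated spike = 1 + this).
#' @param amplitude_by_class Optional named list overriding
#'   `spike_amplitude_fold` per class (used by the comparative multi-class
#'   preset, where non-MD cells have lower amplitude).
#' @param baseline_au Mean per-cell baseline fluorescence (AU).
#' @param baseline_cell_sd Between-cell SD of baseline (AU).
#' @param noise_sd_frac Per-sample Gaussian noise SD as a fraction of the
#'   cell's baseline.
#' @param coupling_by_class Named list of coupling coefficients c in [0, 1]
#'   per class; lone cells must have 0.
#' @param lock_jitter_sd_s SD of per-spike jitter around the drive peak for
#'   drive-locked spikes (s).
#' @param refractory_s Minimum spike separation after drive-locking; closer
#'   spikes are merged (s).
#' @param vaso_rel_amplitude Fractional arteriole-diameter modulation.
#' @param vaso_baseline_um Mean arteriole diameter (micrometres).
#' @param vaso_lag_s Lag of diameter behind Ca2+ (s; 0 = in phase).
#' @param seed Master seed; every random substream derives from it.
#' @return A `plaque_config` object.
#' @export
plaque_config <- function(n_cells = 25,
                          duration_s = 600,
                          fs_hz = 4.0,
                          class_counts = c(pacemaker = 2, follower_high = 6,
                                           follower_med = 10,
                                           follower_low = 6, lone = 1),
                          drive_period_s = 100 / 3,
                          drive_phase_jitter_sd_s = 1.0,
                          isi_gamma_shape = 25,
                          isi_gamma_scale_s = 4 / 3,
                          spike_sigma_s = 0.85,
                          spike_amplitude_fold = 3.0,
                          amplitude_by_class = NULL,
                          baseline_au = 100,
                          baseline_cell_sd = 10,
                          noise_sd_frac = 0.02,
                          coupling_by_class = list(pacemaker = 0.9,
                                                   follower_high = 0.75,
                                                   follower_med = 0.5,
                                                   follower_low = 0.25,
                                                   lone = 0),
                          lock_jitter_sd_s = 0.3,
                          refractory_s = 2.0,
                          vaso_rel_amplitude = 0.1,
                          vaso_baseline_um = 20,
                          vaso_lag_s = 0,
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "plaque_config")
  validate_plaque_config(cfg)
}

validate_plaque_config <- function(cfg) {
  if (!is_count(cfg$n_cells) || cfg$n_cells < 1)
    stopf("n_cells must be a positive integer")
  if (cfg$duration_s <= 0 || cfg$fs_hz <= 0)
    stopf("duration_s and fs_hz must be positive")
  n_frames <- cfg$duration_s * cfg$fs_hz
  if (!is_count(n_frames) || n_frames < 1)
    stopf("fs_hz * duration_s must be a positive integer frame count")
  if (sum(cfg$class_counts) != cfg$n_cells)
    stopf("n_cells (%d) != sum(class_counts) (%d)",
          cfg$n_cells, sum(cfg$class_counts))
  cls <- names(cfg$class_counts)
  if (is.null(cls) || anyDuplicated(cls))
    stopf("class_counts must have unique names")
  cc <- cfg$coupling_by_class
  missing_c <- setdiff(cls[cfg$class_counts > 0], names(cc))
  if (length(missing_c))
    stopf("coupling_by_class missing class(es): %s",
          paste(missing_c, collapse = ", "))
  cvals <- unlist(cc)
  if (any(cvals < 0 | cvals > 1))
    stopf("coupling coefficients must lie in [0, 1]")
  if (!is.null(cc$lone) && cc$lone != 0)
    stopf("lone cells must have coupling 0")
  if (cfg$spike_sigma_s <= 0) stopf("spike_sigma_s must be > 0")
  if (cfg$isi_gamma_shape <= 0 || cfg$isi_gamma_scale_s <= 0)
    stopf("Gamma ISI parameters must be positive")
  cfg
}

#' @export
print.plaque_config <- function(x, ...) {
  cat(sprintf(
    "<plaque_config> %d cells, %.0f s @ %g Hz, drive period %.2f s, ISI Gamma(%g, %g s), seed %d\n",
    x$n_cells, x$duration_s, x$fs_hz, x$drive_period_s,
    x$isi_gamma_shape, x$isi_gamma_scale_s, as.integer(x$seed)))
  cat("  classes:", paste(sprintf("%s=%d", names(x$class_counts),
                                  x$class_counts), collapse = " "), "\n")
  invisible(x)
}

#' Named simulation presets
#'
#' `"wt"` is the wild-type plaque: 25 cells (2 pacemaker, 6 follower_high,
#' 10 follower_med, 6 follower_low, 1 lone), uncoupled inter-spike intervals
#' Gamma(shape 25, scale 4/3 s) with mean 33.33 s (0.03 Hz) and CV 0.2.
#' `"ngfr_ko"` models the NGFR-knockout phenotype: ISI Gamma(shape 2, scale
#' 25/6 s) with mean 8.33 s (4-fold firing-frequency increase) and CV 0.71
#' (irregular), with every coupling coefficient halved (degraded
#' connectivity). `"cc4dp_multiclass"` extends the wild-type plaque with
#' lower-amplitude non-MD cell classes (juxtaglomerular renin and vascular
#' smooth muscle) for cumulative-activity comparisons.
#'
#' @param name One of `"wt"`, `"ngfr_ko"`, `"cc4dp_multiclass"`.
#' @param ... Overrides forwarded to [plaque_config()] (e.g. `seed`,
#'   `duration_s`).
#' @return A `plaque_config`.
#' @export
preset <- function(name, ...) {
  overrides <- list(...)
  base <- switch(
    name,
    wt = list(),
    ngfr_ko = list(
      isi_gamma_shape = 2,
      isi_gamma_scale_s = 25 / 6,
      coupling_by_class = list(pacemaker = 0.45, follower_high = 0.375,
                               follower_med = 0.25, follower_low = 0.125,
                               lone = 0)
    ),
    cc4dp_multiclass = list(
      n_cells = 35,
      class_counts = c(pacemaker = 2, follower_high = 6, follower_med = 10,
                       follower_low = 6, lone = 1, nonmd_jg = 5,
                       nonmd_vsm = 5),
      coupling_by_class = list(pacemaker = 0.9, follower_high = 0.75,
                               follower_med = 0.5, follower_low = 0.25,
                               lone = 0, nonmd_jg = 0, nonmd_vsm = 0),
      amplitude_by_class = list(nonmd_jg = 1.0, nonmd_vsm = 0.4)
    ),
    stopf("unknown preset '%s' (expected wt, ngfr_ko or cc4dp_multiclass)",
          name)
  )
  do.call(plaque_config, utils::modifyList(base, overrides))
}

# Gamma-ISI renewal spike train on (0, duration]. The first spike is placed
# uniformly within one mean ISI so plaques do not all fire at t = 0.
renewal_spike_times <- function(duration_s, shape, scale) {
  mean_isi <- shape * scale
  times <- stats::runif(1, 0, mean_isi)
  # draw ISIs in blocks until past the end
  while (times[length(times)] <= duration_s) {
    k <- max(8L, ceiling((duration_s - times[length(times)]) / mean_isi) + 4L)
    times <- c(times, times[length(times)] +
                 cumsum(stats::rgamma(k, shape = shape, scale = scale)))
  }
  times[times <= duration_s]
}

# Sum of unit Gaussian bumps at `centers` evaluated on `time_s`. Each bump
# only touches +-5 sigma, so evaluation is sparse.
gaussian_bumps <- function(time_s, centers, sigma, amplitudes = NULL) {
  out <- numeric(length(time_s))
  if (!length(centers)) return(out)
  if (is.null(amplitudes)) amplitudes <- rep(1, length(centers))
  fs <- 1 / (time_s[2] - time_s[1])
  half <- ceiling(5 * sigma * fs)
  n <- length(time_s)
  for (j in seq_along(centers)) {
    k <- round(centers[j] * fs) + 1
    idx <- max(1, k - half):min(n, k + half)
    out[idx] <- out[idx] +
      amplitudes[j] * exp(-(time_s[idx] - centers[j])^2 / (2 * sigma^2))
  }
  out
}

#' Simulate one plaque recording
#'
#' Generates raw fluorescence traces for every cell, an in-phase
#' arteriole-diameter trace, and the planted ground truth (classes, coupling,
#' true spike times, latent drive). Identical config and seed give
#' bit-identical output; every random substream is derived from the master
#' seed keyed by (cell index, purpose), so adding cells does not perturb
#' existing ones.
#'
#' @param config A [plaque_config()].
#' @return A `simulated_recording`: list with `traces` ([trace_matrix()]),
#'   `diameter` ([vasomotion_trace()]), `truth` (ground truth list) and
#'   `config`.
#' @export
simulate_plaque <- function(config) {
  cfg <- validate_plaque_config(config)
  n_frames <- as.integer(round(cfg$duration_s * cfg$fs_hz))
  time_s <- (seq_len(n_frames) - 1) / cfg$fs_hz

  # latent drive: jittered impulse train smoothed by the spike kernel
  n_peaks <- floor(cfg$duration_s / cfg$drive_period_s) + 1L
  drive_peaks <- with_local_seed(substream_seed(cfg$seed, "drive"), {
    seq_len(n_peaks) * cfg$drive_period_s -
      cfg$drive_period_s / 2 +
      stats::rnorm(n_peaks, 0, cfg$drive_phase_jitter_sd_s)
  })
  drive_peaks <- sort(drive_peaks[drive_peaks > 0 &
                                    drive_peaks <= cfg$duration_s])
  drive_signal <- gaussian_bumps(time_s, drive_peaks, cfg$spike_sigma_s)

  classes <- rep(names(cfg$class_counts), cfg$class_counts)
  coupling <- vapply(classes, function(cl)
    as.numeric(cfg$coupling_by_class[[cl]]), numeric(1))
  amp <- vapply(classes, function(cl) {
    a <- cfg$amplitude_by_class[[cl]]
    if (is.null(a)) cfg$spike_amplitude_fold else as.numeric(a)
  }, numeric(1))

  values <- matrix(0, n_frames, cfg$n_cells)
  spike_times <- vector("list", cfg$n_cells)
  baselines <- numeric(cfg$n_cells)

  for (i in seq_len(cfg$n_cells)) {
    # participation model: each latent drive event recruits the cell with
    # probability c_i (drive-locked spike at the peak plus lock jitter);
    # independently, a Gamma-ISI renewal train thinned by (1 - c_i)
    # supplies the cell's autonomous firing. Keeps every WT rate equal to
    # the renewal rate (WT renewal mean = drive period) while letting
    # hyperactive, weakly coupled cells lose collective clustering.
    st <- with_local_seed(substream_seed(cfg$seed, "spikes", i), {
      s <- renewal_spike_times(cfg$duration_s, cfg$isi_gamma_shape,
                               cfg$isi_gamma_scale_s)
      if (coupling[i] > 0) {
        s <- s[stats::runif(length(s)) >= coupling[i]]
        recruited <- stats::runif(length(drive_peaks)) < coupling[i]
        locked <- drive_peaks[recruited] +
          stats::rnorm(sum(recruited), 0, cfg$lock_jitter_sd_s)
        s <- c(s, locked)
      }
      s <- sort(s[s > 0 & s <= cfg$duration_s])
      # merge spikes within the refractory separation (keep the earlier)
      if (length(s) > 1) s <- s[c(TRUE, diff(s) >= cfg$refractory_s)]
      s
    })
    spike_times[[i]] <- st

    baselines[i] <- with_local_seed(substream_seed(cfg$seed, "baseline", i),
      max(1, cfg$baseline_au + stats::rnorm(1, 0, cfg$baseline_cell_sd)))
    frac <- 1 + gaussian_bumps(time_s, st, cfg$spike_sigma_s,
                               rep(amp[i], length(st)))
    noise <- with_local_seed(substream_seed(cfg$seed, "noise", i),
      stats::rnorm(n_frames, 0, cfg$noise_sd_frac * baselines[i]))
    values[, i] <- pmax(baselines[i] * frac + noise, .Machine$double.eps)
  }

  cell_ids <- sprintf("cell_%03d", seq_len(cfg$n_cells))
  traces <- trace_matrix(values, cfg$fs_hz, time_s, cell_ids,
                         labels = stats::setNames(classes, cell_ids))

  # vasomotion: smoothed drive (unit peak), shifted by vaso_lag_s
  g <- if (max(drive_signal) > 0) drive_signal / max(drive_signal)
       else drive_signal
  g_shift <- stats::approx(time_s, g, xout = time_s - cfg$vaso_lag_s,
                           rule = 2)$y
  diameter <- vasomotion_trace(
    time_s,
    cfg$vaso_baseline_um * (1 + cfg$vaso_rel_amplitude * g_shift),
    cfg$fs_hz)

  truth <- list(cell_class = stats::setNames(classes, cell_ids),
                coupling = stats::setNames(coupling, cell_ids),
                spike_times_s = stats::setNames(spike_times, cell_ids),
                drive_peak_times_s = drive_peaks,
                drive_signal = drive_signal,
                vaso_lag_s = cfg$vaso_lag_s)

  structure(list(traces = traces, diameter = diameter, truth = truth,
                 config = cfg),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cat("<simulated_recording>\n  ")
  print(x$traces)
  cat(sprintf("  %d planted spikes across %d cells\n",
              sum(lengths(x$truth$spike_times_s)), x$config$n_cells))
  invisible(x)
}

#' Render a recording into a synthetic image stack
#'
#' Each frame is a sum of 2-D Gaussian blobs, one per cell, with integrated
#' intensity proportional to that cell's fluorescence at that frame. The
#' companion label mask assigns every pixel within `3 * blob_sigma_px` of a
#' cell centre to its nearest cell. Lets the ROI-extraction stage be tested
#' end-to-end against known traces.
#'
#' @param recording A `simulated_recording`.
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param cell_centers n_cells x 2 matrix of (row, col) centres; must lie
#'   inside the frame. Centres closer than `2 * blob_sigma_px` trigger an
#'   ROI cross-talk warning.
#' @param blob_sigma_px Blob Gaussian sigma in pixels (> 0).
#' @param poisson_noise If `TRUE`, frames are Poisson-sampled.
#' @param seed Seed for the Poisson noise (defaults to the recording's).
#' @return List with `stack` (frames x rows x cols array) and `mask`
#'   (integer rows x cols matrix, 0 = background).
#' @export
render_image_stack <- function(recording, frame_shape = c(64, 64),
                               cell_centers, blob_sigma_px = 2,
                               poisson_noise = FALSE, seed = NULL) {
  stopifnot(inherits(recording, "simulated_recording"))
  if (blob_sigma_px <= 0) stopf("blob_sigma_px must be > 0")
  vals <- recording$traces$values
  n_cells <- ncol(vals)
  if (n_cells == 0 || is.null(cell_centers) || nrow(cell_centers) == 0) {
    return(list(stack = array(0, c(nrow(vals), frame_shape)),
                mask = matrix(0L, frame_shape[1], frame_shape[2])))
  }
  cell_centers <- as.matrix(cell_centers)
  if (nrow(cell_centers) != n_cells)
    stopf("cell_centers must have one row per cell")
  if (any(cell_centers[, 1] < 1 | cell_centers[, 1] > frame_shape[1] |
          cell_centers[, 2] < 1 | cell_centers[, 2] > frame_shape[2]))
    stopf("cell centers must lie inside the frame")
  if (n_cells > 1) {
    d <- as.matrix(stats::dist(cell_centers))
    diag(d) <- Inf
    if (min(d) < 2 * blob_sigma_px)
      log_warn("render", sprintf(
        "cell centers closer than 2*blob_sigma_px (min %.2f px): ROI cross-talk likely",
        min(d)))
  }

  rr <- matrix(seq_len(frame_shape[1]), frame_shape[1], frame_shape[2])
  cc <- matrix(seq_len(frame_shape[2]), frame_shape[1], frame_shape[2],
               byrow = TRUE)
  # per-cell unit blob (integrates to ~1), flattened for the frame loop
  blobs <- matrix(0, prod(frame_shape), n_cells)
  d2min <- matrix(Inf, frame_shape[1], frame_shape[2])
  mask <- matrix(0L, frame_shape[1], frame_shape[2])
  for (i in seq_len(n_cells)) {
    d2 <- (rr - cell_centers[i, 1])^2 + (cc - cell_centers[i, 2])^2
    blobs[, i] <- as.vector(exp(-d2 / (2 * blob_sigma_px^2)) /
                              (2 * pi * blob_sigma_px^2))
    upd <- d2 < d2min & d2 <= (3 * blob_sigma_px)^2
    mask[upd] <- i
    d2min[upd] <- d2[upd]
  }

  flat <- vals %*% t(blobs)          # frames x pixels
  if (poisson_noise) {
    flat <- with_local_seed(
      substream_seed(seed %||% recording$config$seed, "render"),
      matrix(stats::rpois(length(flat), pmax(flat, 0)), nrow(flat)))
  }
  stack <- array(flat, c(nrow(vals), frame_shape))
  list(stack = stack, mask = mask)
}
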