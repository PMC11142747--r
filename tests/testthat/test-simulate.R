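test_that("presets encode the stated plaque conditions", {
  wt <- preset("wt")
  expect_equal(wt$n_cells, 25)
  expect_equal(sum(wt$class_counts), 25)
  expect_equal(wt$coupling_by_class$lone, 0)
  expect_equal(wt$isi_gamma_shape * wt$isi_gamma_scale_s, 100 / 3,
               tolerance = 1e-12)

  ko <- preset("ngfr_ko")
  # mean ISI ratio KO/WT = 1/4 (4-fold firing-frequency increase)
  expect_equal((ko$isi_gamma_shape * ko$isi_gamma_scale_s) /
                 (wt$isi_gamma_shape * wt$isi_gamma_scale_s),
               1 / 4, tolerance = 1e-12)
  # KO coupling coefficients halved, class by class
  for (cl in names(wt$coupling_by_class))
    expect_equal(ko$coupling_by_class[[cl]],
                 wt$coupling_by_class[[cl]] / 2)

  cc <- preset("cc4dp_multiclass")
  expect_true(all(c("nonmd_jg", "nonmd_vsm") %in% names(cc$class_counts)))
  expect_true(all(unlist(cc$amplitude_by_class) < cc$spike_amplitude_fold))
  expect_error(preset("nope"), "unknown preset")
})

test_that("simulation is bit-identical under a repeated seed, across presets", {
  for (p in c("wt", "ngfr_ko", "cc4dp_multiclass")) {
    a <- simulate_plaque(preset(p, seed = 42, duration_s = 120))
    b <- simulate_plaque(preset(p, seed = 42, duration_s = 120))
    expect_identical(a$traces$values, b$traces$values)
    expect_identical(a$diameter$diameter, b$diameter$diameter)
    expect_identical(a$truth$spike_times_s, b$truth$spike_times_s)
    c2 <- simulate_plaque(preset(p, seed = 43, duration_s = 120))
    expect_false(identical(a$traces$values, c2$traces$values))
  }
})

test_that("config invariants are enforced", {
  expect_error(plaque_config(n_cells = 10), "class_counts")
  expect_error(plaque_config(duration_s = 100.1, fs_hz = 4), "frame count")
  expect_error(plaque_config(coupling_by_class = list(
    pacemaker = 1.2, follower_high = 0.5, follower_med = 0.5,
    follower_low = 0.2, lone = 0)), "\\[0, 1\\]")
  expect_error(plaque_config(coupling_by_class = list(
    pacemaker = 0.9, follower_high = 0.5, follower_med = 0.5,
    follower_low = 0.2, lone = 0.1)), "lone")
  expect_error(plaque_config(spike_sigma_s = 0), "spike_sigma_s")
})

test_that("ground truth is internally consistent", {
  rec <- simulate_plaque(preset("wt", seed = 5, duration_s = 300))
  expect_true(all(rec$truth$coupling[rec$truth$cell_class == "lone"] == 0))
  for (st in rec$truth$spike_times_s)
    expect_true(all(diff(st) > 0))
  expect_true(all(rec$traces$values > 0))
  expect_identical(rec$traces$time_s, rec$diameter$time_s)
})

test_that("noiseless single pacemaker reaches 4-fold baseline at spike peaks", {
  cfg <- solo_config(seed = 2, noise = 0)
  rec <- simulate_plaque(cfg)
  norm <- normalize_traces(rec$traces)
  # isolated true spikes: value at nearest sample to each planted center
  st <- rec$truth$spike_times_s[[1]]
  iso <- st[c(TRUE, diff(st) > 10) & c(diff(st) > 10, TRUE)]
  peak_vals <- vapply(iso, function(s)
    max(norm$values[abs(norm$time_s - s) < 0.5, 1]), numeric(1))
  expect_equal(mean(peak_vals), 4.0, tolerance = 0.01)
})

test_that("uncoupled firing rate converges to the Gamma renewal rate", {
  cfg <- solo_config(seed = 12, duration_s = 10000, noise = 0)
  rec <- simulate_plaque(cfg)
  emp <- length(rec$truth$spike_times_s[[1]]) / cfg$duration_s
  expect_lt(abs(emp - 1 / (25 * 4 / 3)) / (1 / (25 * 4 / 3)), 0.05)
})

test_that("lone cell is statistically independent of the plaque", {
  rs <- sapply(1:20, function(s) {
    rec <- simulate_plaque(preset("wt", seed = s))
    lone <- which(rec$truth$cell_class == "lone")
    other <- setdiff(seq_len(25), lone)[1:8]
    mean(cor(rec$traces$values[, lone], rec$traces$values[, other]))
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("follower coupling shapes pairwise correlation as planted", {
  rec <- simulate_plaque(preset("wt", seed = 7))
  norm <- normalize_traces(rec$traces)
  cl <- rec$truth$cell_class
  r <- pairwise_correlation(norm)$r
  hi <- which(cl == "follower_high")
  lone <- which(cl == "lone")
  hi_pairs <- r[hi, hi][upper.tri(r[hi, hi])]
  hi_lone <- r[hi, lone]
  expect_gt(mean(hi_pairs), mean(hi_lone))
})

test_that("vasomotion tracks the drive with zero lag when unlagged", {
  cfg <- preset("wt", seed = 9, noise_sd_frac = 0,
                drive_phase_jitter_sd_s = 0.5)
  rec <- simulate_plaque(cfg)
  sig <- whole_md_signal(normalize_traces(rec$traces))
  coup <- vasomotion_coupling(sig, rec$diameter)
  expect_lte(abs(coup$lag_s), 1 / cfg$fs_hz)
})

test_that("render/extract round-trip recovers traces (r > 0.99)", {
  cfg <- plaque_config(n_cells = 4, duration_s = 60,
                       class_counts = c(pacemaker = 2, follower_med = 2),
                       coupling_by_class = list(pacemaker = 0.9,
                                                follower_med = 0.5),
                       seed = 4)
  rec <- simulate_plaque(cfg)
  centers <- cbind(c(12, 12, 40, 40), c(12, 40, 12, 40))
  rend <- render_image_stack(rec, c(52, 52), centers, blob_sigma_px = 2)
  got <- extract_roi_traces(rend$stack, rend$mask, cfg$fs_hz)
  expect_equal(ncol(got$values), 4)
  for (j in 1:4)
    expect_gt(cor(got$values[, j], rec$traces$values[, j]), 0.99)
})

test_that("rendering degenerate inputs behave as specified", {
  cfg <- plaque_config(n_cells = 1, duration_s = 10,
                       class_counts = c(pacemaker = 1),
                       coupling_by_class = list(pacemaker = 0),
                       noise_sd_frac = 0, seed = 1)
  rec <- simulate_plaque(cfg)
  # constant trace -> identical frames
  rec$traces$values[] <- 100
  rend <- render_image_stack(rec, c(20, 20), cbind(10, 10),
                             blob_sigma_px = 2)
  for (k in 2:dim(rend$stack)[1])
    expect_equal(rend$stack[k, , ], rend$stack[1, , ])
  # close centers -> cross-talk warning
  cfg2 <- plaque_config(n_cells = 2, duration_s = 10,
                        class_counts = c(pacemaker = 2),
                        coupling_by_class = list(pacemaker = 0), seed = 1)
  rec2 <- simulate_plaque(cfg2)
  expect_message(render_image_stack(rec2, c(20, 20),
                                    cbind(c(10, 11), c(10, 10)), 2),
                 "cross-talk")
  expect_error(render_image_stack(rec, c(20, 20), cbind(30, 10), 2),
               "inside the frame")
})
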