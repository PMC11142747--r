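# mdplaque

Calcium-transient quantification and functional connectomics for
intravital recordings of the renal **macula densa (MD)** — the ~25-cell
salt-sensing plaque at the vascular pole of each glomerulus.

MD cells imaged in vivo with a genetically encoded calcium indicator fire
pacemaker-like Ca²⁺ transients (~0.03 Hz, ~2 s FWHM, ~4-fold F/F0 at the
peak) that cluster into a whole-plaque oscillation in phase with
afferent-arteriole vasomotion. `mdplaque` implements the analysis chain
for such recordings, for renal physiologists and imaging labs:

* **traces** — ROI mean-intensity extraction from image stacks,
  maximum/sum projections, baseline estimation (global or rolling
  percentile), F/F0 normalization, smoothing;
* **transients** — noise-referenced peak detection on F/F0
  (threshold `k·1.4826·MAD` of the sub-threshold residual, prominence and
  2 s separation rules), per-event FWHM via interpolated half-height
  crossings about a local pre-onset baseline, per-cell metrics
  (frequency = count/duration, mean FWHM, mean peak fold, cumulative
  activity `∫ max(F/F0 − 1, 0) dt`), stimulus responses;
* **connectome** — all-pairs Pearson `r` on smoothed, detrended F/F0;
  edges where `r > 0.35` strictly; degree; hub (`degree ≥ mean + SD`,
  `≥ 2`) / lone (`degree = 0`) classification; GraphML and heatmap export;
* **oscillation** — whole-plaque mean signal, dominant frequency (Welch),
  inter-peak-interval CV and spectral entropy as regularity descriptors,
  Ca²⁺–vasomotion cross-correlation lag;
* **simulate** — a coupled-oscillator plaque generator with planted
  ground truth and presets: `"wt"` (Gamma ISI mean 33.33 s, CV 0.2),
  `"ngfr_ko"` (ISI mean 8.33 s — 4× frequency — CV 0.71, coupling
  halved), `"cc4dp_multiclass"` (adds low-amplitude non-MD cell classes).

See `vignettes/mdplaque-methods.Rmd` for the model, parameter rationale,
and limits of what the simulator emulates.

## Worked example

```r
library(mdplaque)

cfg     <- preset("wt", seed = 7)          # 25 cells, 600 s @ 4 Hz
rec     <- simulate_plaque(cfg)
norm    <- normalize_traces(rec$traces)    # F/F0, 20th-percentile baseline
events  <- detect_transients(norm)
metrics <- cell_metrics(events, norm)
round(colMeans(metrics[, c("frequency_hz", "mean_fwhm_s",
                           "mean_peak_fold")], na.rm = TRUE), 4)
#>   frequency_hz    mean_fwhm_s mean_peak_fold
#>         0.0297         2.0046         4.0954
```

The plaque fires at 0.0297 Hz with 2.00 s-wide spikes peaking near
4-fold baseline — the wild-type physiology the simulator plants.
(Mean peak reads 4.10, not 4.00: the lower-tail-mean F0 estimator is
biased ≈ 1.33 σ_noise low; see the vignette.)

```r
corr  <- pairwise_correlation(norm)        # smoothed + detrended F/F0
graph <- threshold_graph(corr, 0.35)       # edge ⇔ r > 0.35 strictly
classify_hub_lone(graph)
#> <cell_classification> 5 hub, 11 regular, 9 lone [mean_plus_sd(param=1)]

oscillation_metrics(whole_md_signal(norm))
#> <oscillation_metrics> dominant 0.0300 Hz, 18 peaks, ISI CV 0.051,
#>                       spectral entropy 0.603
vasomotion_coupling(whole_md_signal(norm), rec$diameter)
#> <coupling_result> lag 0.000 s (Ca2+ leads if > 0), r = 0.951
```

The whole plaque oscillates at 0.03 Hz, highly regular (ISI CV 0.05), in
phase with the arteriole (lag 0 s, r = 0.95). The knockout preset loses
both the regularity and the 0.03 Hz rhythm:

```r
ko <- simulate_plaque(preset("ngfr_ko", seed = 7))
oscillation_metrics(whole_md_signal(normalize_traces(ko$traces)))
#> <oscillation_metrics> dominant 0.0901 Hz, 10 peaks, ISI CV 0.661,
#>                       spectral entropy 0.645
```

## Command line

```sh
inst/cli/mdplaque simulate --preset wt --seed 7 --out sim_wt
inst/cli/mdplaque analyze sim_wt/traces.csv --diameter sim_wt/diameter.csv --out out_wt
inst/cli/mdplaque connectome sim_wt/traces.csv --r-threshold 0.35 --out conn_wt
inst/cli/mdplaque report out_wt/cell_metrics.csv --out report_wt
```

`analyze` runs the full pipeline (normalize → transients → connectome →
oscillation) and writes CSV/JSON/GraphML artifacts plus a
`manifest.json`; identical config + seed gives byte-identical non-image
outputs.

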