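---
title: "Quantifying macula densa calcium physiology and connectivity with mdplaque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macula densa calcium physiology and connectivity with mdplaque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdplaque)
```

## The biological problem

The macula densa (MD) is a plaque of roughly 25 salt-sensing epithelial
cells sitting at the vascular pole of each glomerulus, where it governs
glomerular filtration, renal blood flow and renin release through
tubuloglomerular feedback (TGF). Intravital multiphoton imaging of a
genetically encoded calcium indicator shows that individual MD cells fire
pacemaker-like Ca²⁺ transients — roughly 0.03 Hz, about 2 s full width at
half maximum (FWHM), peaking near 4-fold baseline fluorescence — that
cluster into a whole-plaque oscillation in phase with the vasomotion of the
adjacent afferent arteriole. Cell-to-cell coupling is heterogeneous:
thresholding the pairwise Pearson correlation of the cells' traces reveals
highly connected "hub" cells and isolated "lone" cells, and this
connectivity degrades when neurotrophin signaling through NGFR is knocked
out, alongside a roughly 4-fold rise in single-cell firing frequency and a
loss of whole-plaque rhythm regularity.

`mdplaque` packages that entire analysis as reusable, tested stages, and
pairs it with a ground-truth plaque simulator so every stage can be
validated by recovery of planted structure.

## Pipeline model

**Traces and normalization.** A recording is a frames × cells matrix of
raw fluorescence `F` (from a trace CSV, or extracted from an image stack
as the mean intensity over each ROI label — the mean, not the sum, so ROI
size differences between cells do not act as gains). Activity is expressed
as `F/F0`. The default `F0` estimator is the mean of all samples at or
below the 20th percentile of the trace: with a pacemaker duty cycle of
~2 s spike per ~33 s period, over 90% of samples lie at baseline, so the
lower quintile is spike-free. A rolling variant (60 s centred window,
reflected edges) is available for drifting baselines. Note a known
property of the lower-tail-mean estimator: under Gaussian noise of SD σ it
sits about 1.33 σ *below* the true baseline, so at 2% noise the measured
peak F/F0 of a 4-fold spike reads ≈ 4.10 rather than 4.00. We keep the
estimator because it is maximally robust to spikes; the bias is documented
rather than silently corrected.

**Transient detection.** Detection operates on smoothed `F/F0 − 1`
(moving average, 1 s default). The noise scale is the MAD (×1.4826) of the
sub-threshold residual, re-estimated once after discarding
supra-threshold samples so that spikes cannot inflate it. Candidate peaks
must exceed `k_mad` (default 3) noise SDs, carry topographic prominence of
at least 0.5 on the F/F0 scale, and be separated by at least 2 s — of two
closer peaks the higher survives, ties to the earlier. Peak location is
then refined to the raw-trace maximum within the smoother's half-support
only; a wider refinement window would turn the amplitude into a
max-of-noise statistic with upward bias. FWHM is measured on the raw
normalized trace at half of (peak − local baseline), where the local
baseline is the median of the 5 s preceding onset — so a spike riding on a
plateau measures its own width, not the plateau's. Crossing times are
linearly interpolated; events whose half level is never crossed inside the
event bounds keep their row with `fwhm_s = NA`, and events truncated by
the recording edges count toward frequency but not toward FWHM/peak means.

**Per-cell metrics.** Firing frequency is exactly event count / window
duration. Cumulative activity is the trapezoidal integral of
`max(F/F0 − 1, 0)` — the statistic used to compare MD cells with
neighbouring cell types, which are emulated in the `cc4dp_multiclass`
preset as lower-amplitude classes.

**Connectome.** Pairwise Pearson correlation is computed on smoothed
(1 s) and linearly detrended F/F0, so slow drift cannot fabricate edges;
the preprocessing descriptor is stored with the matrix. Cells i and j are
connected iff `r > 0.35` *strictly* (an exact-threshold value is no edge).
No p-values or multiple-testing machinery: the edge rule is a fixed
cutoff by design. Zero-variance traces yield missing correlations,
treated as non-edges. Lone cells are those with degree 0. Hubs default to
the `mean_plus_sd` rule — degree ≥ mean + 1 SD and ≥ 2 — which is
deterministic and robust to plaque size; when all degrees are equal there
are no hubs (otherwise a complete graph would be all hubs). A
`top_fraction` rule is exposed as the alternative. Both the rule and the
threshold are configuration, because the source observations ("3 hub
cells", "1 lone cell") are ordinal descriptions, not definitions.

**Whole-plaque oscillation.** The plaque signal is the unweighted mean
F/F0 across cells. Rhythm regularity is summarized by the coefficient of
variation of inter-peak intervals and by spectral entropy (Shannon entropy
of the normalized Welch periodogram ÷ log of the bin count; Hann window,
50% overlap, segments spanning four expected periods). "Chaotic-like" is
deliberately operationalized only through these two descriptors — no
Lyapunov or nonlinear-dynamics estimation, since the source usage is
qualitative. Plaque-level peak detection reuses the single-cell detector
with the same 0.5 prominence: in a 25-cell mean one solitary transient
contributes only 3/25 ≈ 0.12, so collective (drive-locked) peaks pass and
single-cell bumps do not.

**Vasomotion coupling.** Ca²⁺ and diameter series are mean-removed,
variance-normalized, and cross-correlated at integer-sample lags (±15 s
default search); positive lag means Ca²⁺ leads. No sub-sample
interpolation: at 4 Hz sampling, one sample (0.25 s) already out-resolves
the "simultaneous" claim being tested. Ties resolve to the smallest |lag|.

## The simulator: a stated world

`preset("wt")` encodes the wild-type plaque: 25 cells (2 pacemaker, 6
follower_high, 10 follower_med, 6 follower_low, 1 lone), Gaussian spike
kernel σ = 0.85 s (so FWHM = 2.3548 σ ≈ 2.0 s), added amplitude 3× baseline
(peak F/F0 = 4), baseline 100 AU with 10 AU between-cell SD, 2% Gaussian
sample noise, and uncoupled inter-spike intervals Gamma(shape 25, scale
4/3 s) — mean 33.33 s (0.03 Hz), CV 0.2. The latent drive is a jittered
impulse train at period 33.33 s (jitter SD 1 s) smoothed by the spike
kernel, so "drive peak phase" is well defined without assuming sinusoids.
Arteriole diameter follows the smoothed drive with 10% relative
modulation and configurable lag (0 = in phase). `preset("ngfr_ko")`
changes exactly two things, per the knockout phenotype: ISI becomes
Gamma(shape 2, scale 25/6 s) — mean 8.33 s, a 4-fold frequency increase,
CV 0.71 — and every coupling coefficient is halved.

**Coupling model.** Each latent drive event recruits each cell with
probability equal to the cell's coupling coefficient `c` (a drive-locked
spike at the peak, lock jitter SD 0.3 s); independently, the cell's
renewal train thinned by `1 − c` supplies autonomous spikes; spikes closer
than a 2 s refractory separation merge. In the wild type, where the
renewal mean equals the drive period, every per-cell rate equals the
renewal rate exactly. We initially implemented the alternative
"per-spike Bernoulli(c) assignment" scheme and rejected it: because it
locks a *fraction of spikes*, the knockout's 4-fold rate increase exactly
cancels its halved coupling (≈ 0.9 locked spikes per cell per drive
period), leaving KO plaques with wild-type-grade regular collective
oscillations — the opposite of the phenotype the simulator exists to
emulate. The participation model is also the standard picture in the
islet hub-cell literature: coupling is the probability of joining a
collective event, not a per-spike relabeling.

Spike bumps add on the fractional scale before multiplying the baseline,
so overlapping spikes exceed the single-spike fold — this is intentional
and mimics plateau behaviour. All randomness flows from one master seed
through named substreams keyed by (purpose, cell index), so adding a cell
never perturbs existing cells and identical configs are bit-identical.

**What the simulator does not emulate** — and therefore what a green
recovery test does not establish: photobleaching, motion, focal drift,
background autofluorescence, indicator saturation and nonlinearity,
genuine IP₃/ER calcium kinetics (bumps are phenomenological), spatially
propagating waves, and closed-loop TGF feedback from vasomotion back onto
the cells. Rendering (`render_image_stack`) provides 2-D Gaussian blobs
with optional Poisson noise purely so the ROI-extraction stage can be
tested end-to-end; image stacks live in memory as arrays (this
environment has no TIFF library, and traces — the scientific payload —
travel as CSV/JSON).

## Numerical choices and degenerate inputs

* Frames are 0-based; `time_s(k) = k / fs_hz`; all windows are half-open
  `[t0, t1)`. Default sampling 4 Hz resolves the 2 s FWHM with ≤ 0.25 s
  quantization.
* Smoothing windows round to odd sample counts; all filters pad by
  reflection and preserve length and time axis.
* A constant trace yields `F0` equal to its value (logged), normalizes to
  exactly 1, and produces zero events.
* Zero-variance cells in the connectome: missing correlations, non-edges,
  eligible only for lone/regular.
* Recording durations and frame rates of the original experiments are not
  public; defaults (600 s at 4 Hz) were chosen for numerical adequacy —
  ~18 oscillation periods, enough for stable correlation estimates — not
  as a claim about the acquisitions.

## Known limitations

Detected frequency saturates when inter-spike intervals approach the
event width: at the knockout firing rate (mean ISI 8.33 s, CV 0.71, spike
FWHM 2 s), ~6% of spikes merge into single bumps and several more percent
fall to the 2 s separation / 0.5 prominence rules, so the detected KO/WT
frequency ratio reads ≈ 3.4 rather than the planted 4.0. This is a
property of any peak-counting measurement at these rates, reproduced by
an ideal continuous-time detector, and is reported as measured. The F0
estimator bias under noise (above) is the other known systematic;
both are characterized in the test suite rather than hidden.
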