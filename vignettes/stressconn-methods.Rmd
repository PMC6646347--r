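---
title: "Methods: cardiac susceptibility scoring and cortical connectivity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac susceptibility scoring and cortical connectivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acute social stress produces markedly different cardiac responses across
individual rats: some develop arrhythmias (skipped heartbeats) and elevated
heart-rate variability (HRV) after a defeat episode, others do not. This
package implements an analysis chain that (1) scores that cardiac response
from ECG and classifies each animal as *susceptible* or *resilient*, and
(2) asks whether the functional organization of the cortex **before** the
stressor — pairwise correlations of local field potential (LFP) band power
across six cortical regions (PL, S1, PPC, HPC, RSC, V1) — predicts the
label, using distribution comparisons, PCA, and a linear SVM under
leave-one-out cross-validation (LOOCV). Because no public recordings
accompany this analysis, a synthetic multichannel biosignal generator with
known ground truth is a first-class part of the package: every claim the
test suite makes is a parameter-recovery or calibration claim against that
generator.

## Cardiac scoring

**R-peak detection.** The ECG is bandpass filtered at 20–200 Hz (4th-order
Butterworth, zero-phase via forward–backward filtering), then smoothed with
a Gaussian kernel whose SD equals the R-wave template width (5 ms). The
smoothing stage is a matched filter: without it, additive noise at
amplitude SNR 10 displaces the detected peak by ~4 ms SD, which inflates
the measured RR coefficient of variation by ~12% relative; with it the
jitter is ~0.4 ms and the configured CV is recovered within a few percent.
Peaks are local maxima above 0.5× the 98th percentile of the smoothed
absolute amplitude, with an 80-ms refractory period (rat RR intervals are
≥ ~130 ms); within a refractory conflict the larger peak wins.

**Arrhythmia rule.** A skipped beat roughly doubles the local RR interval.
An event is flagged when an interval exceeds 1.5× the running median RR in
a centered 60-s window — midway between normal jitter and a doubled
interval, and invariant to a uniformly slow or fast heart. The event time
is the midpoint of the long interval. The threshold is strict (`>`).

**Per-minute metrics and deltas.** The arrhythmia rate is an event count
per 1-min bin. HRV is the coefficient of variation (population SD over
mean) of the RR intervals whose *left* R-peak falls in the bin; bins with
fewer than two intervals yield missing HRV and are excluded from means.
Delta metrics subtract the mean over the last 10 min of the pre session
from the mean over the first 30 min of the post session.

**Classification.** A rat is susceptible iff `delta_arr > 0.2` events/min
**or** `delta_hrv > 0.02` (both strict, reading "more than" literally:
values exactly at threshold are resilient). ΔHRV is treated as a unitless
CV difference.

## EMG sleep scoring and locomotion

The EMG is mean-subtracted once per session and its rms computed in 500-ms
bins. The sleep threshold is `mean − SD`, where both statistics are taken
over the rms values lying between their 20th and 80th percentiles — a
trimmed band robust to the low-amplitude sleep tail and high-amplitude
movement artifacts. (The alternative reading, the upper 20–80% of the
sorted range, is less robust to artifacts and was not adopted.) Sleep
periods are maximal runs of bins strictly below threshold lasting ≥ 10 s.
Because the threshold is built from trimmed moments of the rms itself, it
is invariant to a global gain on the signal — a property the tests check
directly. Locomotion speed is per-frame Euclidean displacement over the
~333-ms frame interval of the 3-Hz position track.

## LFP spectral analysis and connectivity

LFP channels are low-passed at 80 Hz (8th-order Butterworth, zero-phase)
and decimated to 200 Hz, then cut into non-overlapping 5-s windows. Each
window is mean-removed, Hann-tapered, and Fourier transformed; one-sided
power is kept on a 0.2 Hz grid restricted to [1, 45) Hz. Five bands —
delta [1, 4), a middle 4–6 Hz band, theta [6, 10), beta [10, 25), gamma
[25, 45) — are half-open so they partition [1, 45) exactly; band power is
the bin sum, and the partition identity (five band powers summing to total
[1, 45) power per window) is asserted in the tests. Window mean removal
makes the spectrogram invariant to DC offsets, which would otherwise leak
through the taper into the lowest bins. Non-overlapping windows and the
Hann taper are analysis choices; raw (not log) band power is correlated
downstream.

Functional connectivity is the Pearson correlation of two regions'
per-window band-power series, aligned by window index; a 30-min pre
session yields 360 windows. Pairs involving an unrecorded region are
missing; a zero-variance series yields a missing value with a diagnostic
rather than NaN.

## Group statistics

Pooled pair correlations (each rat with *k* recorded regions contributes
`choose(k, 2)` observed pairs; 60 susceptible and 66 resilient pairs under
the recorded missing-region configuration) are compared between groups per
band with the two-sample Kolmogorov–Smirnov test, using the asymptotic
two-sided p-value. Pooling treats pairs from the same rat as independent
observations; that is a property of the pooled design this package
reproduces, not a claim we defend — the LOOCV analysis, which operates per
rat, does not share it. Average spectra are compared per 0.2-Hz bin with
pooled-variance Student's t-tests followed by Benjamini–Hochberg FDR
across bins (zero-variance bins are flagged and excluded); behavioral
scalars use Student's t with capped Bonferroni correction.

## Imputation, PCA, and the SVM

Missing pairs are filled with the mean of the observed same-group values
for that pair and band, after restricting to pairs that have at least one
donor per group (all 15 for the full cohort). Imputation runs once on the
full cohort *before* LOOCV, mirroring the described analysis order; this
leaks a small amount of label information into held-out folds and is
documented rather than silently fixed.

PCA (mean-centered, covariance eigendecomposition via `prcomp`) supplies
three component scores and contribution ratios for visualization only. The
SVM is trained on the full 15-dimensional pair-correlation vector — not on
PCA scores — because the analysis reports one weight per region pair,
which requires the raw feature space. Features are z-scored within each
training fold; the soft-margin cost is C = 1 (both unstated upstream;
fixed a priori, not tuned). Weights and bias are reported on the original
feature scale with a fixed sign convention (positive decision value = first
factor level), independent of libsvm's order-of-appearance convention.
LOOCV retrains on each fold of n−1 rats and predicts the held-out rat;
failure is `100 × misclassified / n`, always a multiple of `100/n`. A fold
reduced to a single class predicts that fold's majority class.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the biophysics of the signals:

* **ECG** — RR intervals are truncated-normal draws (mean 0.2 s, i.e.
  300 bpm; SD = CV × mean; symmetric truncation to (0, 2·mean) preserves
  the mean and keeps normal jitter clearly below a doubled interval).
  Arrhythmias arrive as a Poisson process (events/min) and each deletes one
  interior beat — a skipped R-peak that locally doubles the RR interval.
  The waveform is a unit Gaussian R-wave (SD 5 ms) at each surviving beat
  plus white noise; the default noise SD 0.1 gives amplitude SNR 10.
* **EMG** — alternating wake/sleep bouts with exponential durations
  (means 120 s / 60 s), white noise scaled to the state rms (1.0 / 0.2);
  true sleep intervals are returned exactly.
* **LFP** — per band, each region's power envelope at 5-s resolution is
  log-normal, `exp(sigma·g)` with sigma = 0.5, where
  `g = sqrt(rho_lat)·z_common + sqrt(1 − rho_lat)·z_region` shares a single
  latent factor per band. Two constructions matter for honest parameter
  recovery: (1) `rho_lat` is the log-normal inverse
  `log(1 + rho(e^{sigma^2} − 1))/sigma^2` of the target correlation, so the
  *power* envelopes have Pearson correlation exactly `rho` in expectation
  (the naive construction biases recovered correlations by up to −0.12 at
  rho = 0.6); and (2) the band-limited carrier under each envelope —
  synthesized in the frequency domain — is normalized to unit
  *Hann-weighted* power per 5-s window, because that is precisely the
  quantity the tapered spectrogram measures; normalizing raw RMS leaves
  chi-square window-power fluctuation that attenuates recovered
  correlations by ~15%. Carrier amplitudes decrease with frequency
  (1, 0.8, 0.8, 0.5, 0.3 for delta…gamma) and 1/f background noise
  (SD 0.5 over 1–100 Hz) is added.
* **Cohort** — 5 susceptible and 6 resilient rats, 30-min pre and 120-min
  post sessions. Susceptible rats' post sessions use arrhythmia rate
  0.4/min and RR CV 0.07 (deltas ≈ 2× the 0.2/min and 0.02 thresholds, so
  classification is unambiguous at the stated margins); resilient rats are
  unchanged. Resilient rats carry theta rho = 0.6 vs susceptible 0.25;
  all other bands share rho = 0.3 in both groups, so only theta should
  separate. The default missing-region plan reproduces the recorded
  configuration (one region missed in 3 + 3 rats, two in 1), giving the
  60/66 pooled pair counts. Per-rat seeds derive deterministically from the
  cohort seed, so rats can be generated one at a time (bounded memory) with
  results identical to batch generation, and a fixed seed reproduces the
  cohort bit-exactly.

What the generator deliberately does **not** emulate: realistic ECG
morphology (P/T waves), respiratory sinus arrhythmia, circadian structure,
REM/NREM architecture, the 1/f-dominated shape of real LFP spectra,
per-pair heterogeneity of connectivity (a single latent factor gives every
pair the same rho), or any coupling between connectivity and the cardiac
deltas beyond group membership. Passing tests therefore demonstrate that
the pipeline recovers the parameters of this statistical structure — not
that it would behave identically on recorded data with artifacts,
non-stationarity, and region-specific coupling.

## Numerical choices and degenerate inputs

* Estimation windows: sampling-rate ratios for decimation must be integer;
  spectrogram frequency resolution (0.2 Hz) is fixed by the 5-s window.
* Strict inequalities throughout (susceptibility thresholds, arrhythmia
  factor, sleep threshold), reading "more than"/"less than" literally.
* Population (n) SD for HRV; sample SD for the sleep threshold band.
* RR-interval-to-bin assignment: an interval belongs to the bin containing
  its left R-peak.
* Degenerate inputs report rather than crash: flat ECG yields an empty
  beat series; constant rms yields no sleep (SD 0 means nothing is
  strictly below threshold); zero-variance connectivity series yield
  missing entries with diagnostics; zero-variance spectral bins are
  excluded from FDR; identical groups test as t = 0, p = 1.
* Session containers store channels as little-endian doubles (bit-exact
  round trip) or a documented CSV dialect; short sessions validate with a
  warning, not an error, so seconds-long fixtures remain analyzable.

## Problem sizes used by the tests and acceptance script

The validation suite keeps the stated group structure, effect sizes, and
thresholds, and scales only durations and sampling rates: cardiac recovery
uses full 30-min ECG at 1 kHz; connectivity recovery uses 30-min LFP
(360 windows, the pre-session condition) at 400 Hz–1 kHz carrier rates;
cohort-level runs use 11–15-min pre and 31-min post sessions at 400–500 Hz
for the in-suite checks and 30-min sessions at 1 kHz in the acceptance
script. Post-session LFP is generated only where a run analyzes it. One
statistical note: at 360 windows the per-pair Pearson estimate has
intrinsic sampling SD ≈ 1/√360 ≈ 0.053, so recovery assertions are made on
across-pair means (SD ≈ 0.02), not on individual pairs, which would fail a
±0.1 band a few percent of the time by sampling noise alone.

## Known limitations

* The susceptibility rule, arrhythmia criterion, and sleep rule are fixed
  rules with stated constants, not fitted models; they are only as good as
  those constants on new data.
* Whole-cohort imputation before LOOCV leaks group means; with 11 rats the
  alternative (in-fold imputation) is noisier, and the package keeps the
  described order.
* The pooled KS test inherits the pairs-as-independent assumption of the
  pooled design.
* Asymptotic KS p-values are used even at n = 60/66; exact small-sample
  p-values are out of scope.
* The generator's equal-rho-per-pair construction cannot probe which
  *specific* pairs drive classification; SVM weight maps on synthetic
  cohorts are therefore diagnostics, not biological claims.
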