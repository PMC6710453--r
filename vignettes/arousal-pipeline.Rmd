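---
title: "From raw signals to Bayes factors: the arousal analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw signals to Bayes factors: the arousal analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msarousal)
```

This vignette documents every algorithmic choice in the pipeline: what is
computed, with which parameters and units, why those defaults, and where
the known limits are.

## The design

Two groups write brief answers to two open-ended questions — about their
own death (mortality salience, MS, n = 53) or about dental pain (DPS,
n = 55) — embedded in a fixed protocol: four 1-minute baselines (BL1–BL4),
the first question (Q1, self-paced, ~80 s), a 1-minute rest (R1), the
second question (Q2), and six 1-minute recovery intervals (R2a–R2f).
Nine indicators are derived per segment: HR (bpm), MAP (mmHg), lnHF and
lnLF heart-rate-variability power (ln ms²), RR (cycles/min), NSFR
(fluctuations/min), PEP (ms), CO (l/min), and TPR (mmHg·min/l).

Analysis cells are baseline-change scores. MAP comes from three spot
readings (baseline, after R1, after R2f), so MAP itself is analyzed only at
R1 and R2f; the reading nearest in time backs TPR everywhere. That gives
8 × 9 + 2 = 74 cells, each tested once against baseline (within) and once
between conditions — 148 comparisons.

## Signal conditioning

* **ECG**: 0.5 Hz high-pass (baseline wander), 40 Hz low-pass, 48–52 Hz
  band-stop (mains), resampled to 400 Hz. All filters are zero-phase
  (forward–backward Butterworth), because R-wave and B-point latencies feed
  PEP directly and phase delay would bias them.
* **dZ/dt**: mains band-stop only, resampled to 1000 Hz; the ensemble
  average, not a filter, isolates the beat-locked waveform.
* **Respiration belts**: 1 Hz low-pass, resample to 25 Hz, 0.033 Hz
  high-pass for belt drift.
* **EDA**: resampled to 25 Hz (anti-aliased when downsampling), otherwise
  untouched — the fluctuation rule operates on absolute microsiemens.

Resampling is cubic-spline interpolation onto the target grid; every
channel is low-passed well below the target Nyquist first, so the spline is
operating on a smooth function and any rate ratio is supported.

## Beat detection and HRV

R waves are found Pan–Tompkins style: 5–15 Hz band emphasis, squared
derivative, 150 ms moving-window integration, adaptive signal/noise
threshold with a 250 ms refractory period, and refinement to the local ECG
maximum. A flat channel returns an empty, flagged series rather than silent
zeros, and an edit list (add/delete times) mirrors manual correction.

Heart period over a window is the mean of inter-beat intervals whose
midpoints fall inside it (half-open windows throughout). For HRV the IBI
series is cleaned (artifact-flagged intervals linearly interpolated when at
most two consecutive; longer runs void the window), resampled to 4 Hz by
cubic spline, and passed through a Welch estimator (Hann window, 60 s
segments, 50% overlap, per-segment linear detrend, one-sided density).
Band powers integrate 0.14–0.4 Hz (HF) and 0.07–0.14 Hz (LF) and are
natural-logged after flooring at 1e-6 ms², so a pathological zero-variance
series yields a finite, flagged value instead of -Inf. Windows shorter than
60 s are missing by construction — one LF cycle at 0.07 Hz is ~14 s, and a
60 s support is the shortest honest segment for these bands.

## Impedance cardiography

Per window, dZ/dt sweeps from −100 to +500 ms around each R wave are
combined by the pointwise **median** (robust to occasional corrupted
beats); fewer than 10 beats voids the window. On the ensemble:

* **Z** is the maximum in 30–300 ms after R.
* **B** (aortic valve opening) is the earliest point reaching 95% of the
  peak second derivative within 150 ms before Z, restricted to where the
  ensemble sits below 40% of the Z amplitude. The second derivative is
  taken on the unsmoothed median ensemble: ensemble averaging has already
  suppressed noise, and smoothing was observed to bias B late by several
  milliseconds, which PEP (tolerance ±2 ms) cannot afford. The 95%-reach
  criterion rather than the argmax removes the discrete-grid bias of
  scoring a flat curvature peak.
* **X** (aortic valve closure) is the minimum within 450 ms after Z and
  must be an interior local minimum — a monotone ensemble has no X notch
  and is flagged missing rather than scored at the window edge.

PEP = B + 20 ms (Q fixed 20 ms before R), LVET = X − B, and stroke volume
follows Kubicek: SV = 135 Ω·cm × (L/Z0)² × LVET × (dZ/dt)max, with L the
electrode distance and Z0 the mean basal impedance over the window.
CO = SV × HR / 1000; MAP = sys/3 + 2·dia/3; TPR = MAP/CO.

## Respiration and electrodermal activity

Respiratory cycles are median crossings of the drift-free belt signal with
two guards: a crossing must be followed within 1 s by an excursion of at
least 15% of the robust signal amplitude (rejects filter edge ripple), and
cycles are at least 1 s apart. Rates are averaged over the belts that
produced usable data.

A nonspecific fluctuation (NSF) requires a local-minimum onset (onsets at
least 1 s apart) followed by a local maximum 3.5–12 s later whose rise
strictly exceeds 0.02 µS. The event belongs to the segment containing its
onset even when the peak falls in the next segment; windows under 10 s
yield a missing rate rather than a noisy one.

## The synthetic cohort

The generator has two modes, because the statistics and the signal
processing operate at different scales:

* **`mode = "signals"`** renders full recordings from per-participant
  ground truth: Gaussian-bump QRS-T complexes at beat times driven by
  LF/HF-modulated inter-beat intervals; a raised-cosine dZ/dt systolic
  complex with B at R + (PEP − 20) ms and an X notch at B + LVET;
  quasi-sinusoidal belts; and an EDA trace of tonic level, slightly
  negative drift (−0.01 µS/min, so fluctuation onsets remain local
  minima), and bi-exponential skin-conductance responses (rise 2.5 s,
  decay 7 s). SCR events are spaced ≥30 s with amplitudes in 0.15–0.4 µS:
  at that spacing the preceding decay tail can neither mask a rise nor
  drag the superimposed peak below the 3.5 s window floor, so clean-signal
  NSF counts are exactly recoverable — a deliberate property of the
  generator, since it exists to provide unambiguous ground truth.
* **`mode = "segments"`** (the default) draws the participant-by-segment
  table directly: per-participant levels from documented population
  normals, per-minute noise chosen as change-SD/√1.25 so that
  baseline-change scores (post − mean of four baseline minutes) hit the
  target dispersions. Those targets (e.g. 2.9 bpm for HR, 0.83 for lnHF,
  21.5 ms for PEP) are calibrated so pooled standard errors at n = 108
  land near the published ones. This mode costs milliseconds per cohort
  and carries exactly the structure the inference consumes, which is what
  makes 200-replicate calibration studies affordable; the signals mode
  validates that the derivation chain reaches the same table.

Defaults replicate the study conditions: 53/55 participants, no condition
effects, 13.92% of post-baseline cells missing completely at random.
Effects are injected additively per parameter × segment for MS
participants only.

Realism limits, stated plainly: no ectopy or movement artifacts, no
respiratory sinus arrhythmia coupling between the belts and the IBI
modulation, sinusoidal rather than sampled-waveform respiration, and a
stationary tonic EDA. These are sufficient for round-trip validation, not
for detector stress-testing.

## Missing data

Imputation is chained predictive mean matching: each incomplete column is
regressed on all other cells plus the condition indicator; a Bayesian
parameter draw (ridge-stabilized normal-inverse-chi-squared) predicts the
missing rows; each missing cell takes the observed value of one of the
k = 5 donors with nearest predicted means. Five completed copies, five
sweeps each. Estimates are pooled by Rubin's rules with Barnard–Rubin
degrees of freedom.

A measured consequence of this (pinned) predictor set: with 74 columns and
~93 observed rows per column at 14% missingness, the regressions overfit,
between-imputation variance inflates (relative increase in variance ~0.27
against ~0.16 for a well-specified model), and the pooled between-group
test becomes conservative — ~2.7% uncorrected false positives instead of
5% under the null design, while the identical pipeline at zero missingness
is nominal (4.7% measured over 60 replicates). This is the textbook
behavior of Rubin pooling under a noisy imputation model, not an
implementation artifact, and it is asserted honestly in the test suite.

## Inference

Within-family tests are one-sample t tests on change scores; between-family
tests are pooled-variance two-sample t tests (MS − DPS). Per-imputation
statistics are pooled, the pooled t is converted to a two-sided p at the
pooled df, and p values are Benjamini–Hochberg adjusted over the returned
family. Bayes factors use the JZS setup: a Cauchy(scale r = 1) prior on the
standardized effect, represented as a normal mixed over an
inverse-gamma(1/2, 1/2) hyperparameter g and integrated by adaptive
quadrature on u = g/(1+g) in log space (relative tolerance 1e-8; the suite
checks it against a brute-force trapezoid oracle to 1e-4). Evidence is
"alternative" above 3, "null" below 1/3, else inconclusive.

One reproduction subtlety is worth recording. The study's tabled Bayes
factors — in both families — follow the **two-sample** JZS formula at group
sizes 53/55; the characteristic ~0.15 floor of near-zero-t cells is exactly
the two-sample floor at those sizes, and tabled values such as 0.20 (CO Q1)
and 0.37 (MAP R1) are reproduced to three digits from the printed mean/SE
pairs by that route (`published_study_bf()`). The package's own
within-family analysis defaults to the one-sample formula, which is the
statistically conventional choice for segment-versus-baseline contrasts;
`bf_within = "two_sample"` switches to the tabled convention. Separately,
Bayes factors at large t are super-exponentially sensitive to t: at
t ≈ 3.9 the two-decimal printing of a mean/SE pair (−0.93/0.24) moves the
recomputed value by ~12% (118.97 vs the tabled 106.23; the unrounded SE
~0.242 reproduces it), so that one cell is not recoverable from printed
inputs at 5% tolerance by any route.

The sensitivity analysis inverts the noncentral-t power function by root
search: the minimal detectable effect at α = .05 and power .80 is
dz = 0.27 within (n = 108) and d = 0.54 between (53/55).

## Problem sizes

The shipped defaults are package choices sized to the design they mirror:
148 comparisons, m = 5 imputations × 5 sweeps, k = 5 donors, Cauchy scale
1, FDR at the 148-test family, and 1-minute analysis windows (60 s is the
HRV floor; question segments use their actual span, minimum 30 s, with HRV
missing below 60 s). Replication-scale runs (hundreds of simulated
cohorts) are feasible because the segments mode bypasses signal rendering.

## Limitations

Beyond the generator realism notes above: the B-point criterion is tuned
for the rendered raised-cosine morphology class and validated by round
trip, not against scored human ICG; the FDR step is plain
Benjamini–Hochberg (an empirical-null variant would need a density
estimate the package deliberately does not ship); and the imputation
conservatism described above is inherent to the pinned all-predictors
model at this n/p ratio.
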