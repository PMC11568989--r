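---
title: "Methods: accelerometer gait features and fall-risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer gait features and fall-risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfall)
```

## The problem

Falls in older adults are common, costly, and hard to screen for: the
questionnaire- and stopwatch-based clinical instruments in routine use are
subjective and have limited predictive validity. A single waist-worn
tri-axial accelerometer recorded during a short walk at a self-selected pace
is cheap, objective, and tolerable for the patient. **gaitfall** implements
a complete analysis pipeline that turns such a recording — vertical (V),
mediolateral (ML), and anterior–posterior (AP) acceleration in g at a known
sampling rate — into a faller / non-faller classification, together with a
synthetic gait generator so that every stage can be exercised and validated
without access to clinical data.

The pipeline has four stages: signal conditioning, feature extraction
(a fixed registry of 168 features), ReliefF feature weighting swept over
neighbor counts, and a small multilayer perceptron evaluated under
stratified 10-fold cross-validation with pooled confusion-matrix metrics.

## Signal conditioning

Each axis is processed identically (`preprocess_recording()`):

1. **3-sample median filter** (`median_filter3`) suppresses isolated
   single-sample spikes. The window shrinks at the record edges, so the
   first and last samples pass through unchanged — the choice affects two
   samples out of thousands.
2. **Gravity removal** (`remove_gravity`). Gravity and slow postural drift
   are estimated by a zero-phase order-2 Butterworth low-pass at 0.25 Hz of
   the mean-removed signal and subtracted, leaving body acceleration.
   Low-passing the *mean-removed* signal makes the estimator exact for
   constant inputs and numerically benign at the very low normalized
   cutoff. Any residual below 0.5 Hz is removed again by the bandpass high
   edge, so the precise cutoff is uncritical.
3. **Two zero-phase bandpass versions.** A 0.5–3 Hz version (`band_step`)
   isolates the step-frequency band and is used *only* for step detection;
   a 0.5–15 Hz version (`band_analysis`) carries essentially all walking
   energy and is used for every feature. Filters are order-4 Butterworth
   designs applied forward and backward (`signal::filtfilt`) over an
   odd-reflection pad of three low-edge periods. Forward–backward
   application squares the magnitude response and cancels the phase, so
   step-peak timing is unbiased; the realized response passes a 2 Hz tone
   within 5%, rejects DC below 1%, and leaves a 25 Hz tone below 2% RMS at
   100 Hz sampling.
4. **Max-normalization** (`normalize_max`): each axis of each version is
   divided by its maximum absolute value, so downstream thresholds (e.g.
   the step-peak height) are amplitude-free. An all-zero axis is an error,
   reported with the axis name.

## Step detection and gait-cycle timing

Steps are local maxima of the normalized 0.5–3 Hz vertical axis
(`detect_steps`). Two constants regularize the peak picker, both
physiological rather than statistical: a minimum peak height of 0.2 on the
normalized signal and a minimum separation of 0.25 s (cadence ≤ 240
steps/min), resolved greedily by descending height so multi-lobed peaks are
not double counted. Peak-to-peak intervals are step durations; consecutive
non-overlapping pairs are stride durations; intervals outside 0.25–2.5 s
are treated as detector artifacts and excluded from duration statistics
(the peaks themselves are kept, so a single missed peak does not discard a
subject). Fewer than 8 accepted peaks is an error. The three gait-cycle
features are the mean step duration, mean stride duration, and cadence
`60 / mean(step duration)` in steps per minute.

## The 168-feature registry

`feature_registry()` fixes the names and order: 3 gait-cycle features,
6 cross-axis features, and 53 per-axis features (21 time-domain + 32
frequency-domain) for each of V, ML, AP — 168 in total, all computed from
the 0.5–15 Hz version except the gait-cycle timings.

**Cross-axis block.** Pearson correlation and sample covariance (n−1) for
the three axis pairs, computed on the full normalized signals.

**Time domain (per axis).** Sixteen per-step statistics averaged across
step slices (mean, sd, skewness, Pearson kurtosis m₄/m₂², RMS, range,
median, IQR, mean and sd of the first and last half-step, zero-crossing
rate, mean-square energy, mean absolute value, mean absolute deviation) and
five whole-signal features: the coefficient of variation of per-step peak
amplitudes, step and stride regularity, their ratio, and the mean trend.
Step slices are half-open intervals between consecutive peaks; an odd
middle sample joins the first half.

*Step/stride regularity* (`autocorr_regularity`) is the unbiased
autocovariance about zero normalized by its lag-0 value, evaluated at the
mean step and stride lags. Because the discrete lag grid rarely contains
the true period, the value is the maximum over lags within ±10% of the
nominal lag. Values near 1 mean highly repeatable gait; white noise scores
near 0. The regularity ratio uses a sign-preserving denominator clamp at
1e-6 so the feature stays finite on noise-like signals.

*Mean trend* (`mean_trend`) is the mean absolute value of a moving average
whose window is the mean step duration: zero for stationary gait, growing
with slow amplitude drift — a summary of step-scale variability.

**Frequency domain (per axis).** The PSD is a single whole-record
periodogram with a Tukey window of cosine fraction 0.5
(`periodogram_tukey`), one-sided density scaling, and all features read
only the 0.5–15 Hz band. The two most prominent in-band peaks (scipy-style
prominence by walk-down to the higher surrounding minimum; width at half
prominence, linearly interpolated) give frequency, amplitude, width and
prominence descriptors F1/F2; if the spectrum has fewer than two local
maxima the second descriptor falls back to zeros. Audio-style shape
descriptors (centroid, spread, standardized weighted skewness and kurtosis,
flatness = geometric/arithmetic mean, crest = max/mean, decrease, slope,
95% rolloff, normalized entropy) are complemented by summary statistics of
the in-band power values, of the lower (0.5–7.75 Hz) and upper
(7.75–15 Hz) half-bands — the band midpoint defines the split — relative
power in 0.5–3, 3–8 and 8–15 Hz, total band power, the F2/F1 amplitude
ratio, and the median frequency.

## Feature selection: ReliefF

`relieff_weights()` implements deterministic all-instances two-class
ReliefF: each subject in turn contributes its K nearest same-class
neighbors (hits) and K nearest other-class neighbors (misses) under
Manhattan distance over all features; a feature's weight falls by the mean
hit difference and rises by the prior-weighted mean miss difference. On
min-max-scaled features every weight lies in [−1, 1], and a feature
identical to the label reaches weight 1. Distance ties break by ascending
subject index, so the weighting is a pure function of the data — verified
against an independently coded exhaustive oracle to 1e-12 on small
datasets. When K exceeds what a class can supply, the neighbor count caps
at availability (with the matching divisor), the usual convention that lets
the K sweep run past the smaller class size.

The selection procedure is a two-dimensional sweep (`selection_sweep`):
neighbor counts K = 1..40, each producing one weighting, crossed with
retained-feature counts N = 5..40 (nested prefixes of the ranking), each
cell evaluated by the classifier below. Scaling for the classifier is
re-fit inside each training fold; the ReliefF weighting itself, following
the reference study design, is computed once on the full cohort (see
*Limitations*).

## Classification and evaluation

The classifier (`train_mlp`) is a single-hidden-layer perceptron: ReLU
hidden units, a sigmoid output scoring the faller class, log loss with L2
penalty α = 1e-4, at most 200 epochs, batch size min(200, n). The solver is
Adam (learning rate 1e-3, betas 0.9/0.999) — the stochastic gradient-based
optimizer that reference neural-network toolkits use by default; classical
momentum SGD is available via `solver = "sgd"`, but at 200 epochs and this
learning rate it demonstrably undertrains even trivially separable data,
while Adam attains training accuracy 1.0 there. Training runs in compiled
code with its own RNG, so a model is a pure function of (data, config,
seed). The hidden-layer width is swept over 10, 20, …, 200 by default.

Evaluation (`cross_validate`) uses stratified folds (per-class round-robin
dealing after a seeded shuffle, so per-fold class counts deviate from the
global proportion by at most one subject). Min-max scaling is fit on the
training folds only. All out-of-fold predictions are pooled into a single
TP/FN/FP/TN table from which accuracy, sensitivity (faller recall) and
specificity are computed — pooling, not per-fold averaging, is what makes
the integer confusion counts sum to the cohort totals — and AUC is the
Mann–Whitney statistic of the pooled out-of-fold scores. Model selection
over the (K, N, hidden) grid is lexicographic: maximize accuracy, then
sensitivity, then prefer fewer features, fewer hidden units, smaller K.
The sensitivity-then-parsimony order encodes the screening context: missing
a faller is the expensive error.

## The synthetic cohort generator

`generate_subject()` emulates a one-minute waist-accelerometer walk as a
harmonic series on the stride frequency (half the step frequency):
per-axis amplitudes for stride-harmonics 1–4, with V and AP power
concentrated at the step frequency (harmonic 2) and ML at the stride
frequency (harmonic 1), matching standard gait biomechanics. Step periods
are drawn per step as `(1/f_step)(1 + ε)`, ε ~ N(0, timing jitter), the
stride phase advancing continuously across steps; each step carries a
common amplitude scale 1 + N(0, amplitude jitter); white noise is added;
V carries a 1 g gravity offset. `generate_cohort()` draws each subject's
step frequency from U[1.6, 2.1] Hz (a normal self-selected pace) and labels
subjects from two jitter regimes — non-fallers 2%/5% and fallers 8%/15%
(timing/amplitude), mirroring the clinical observation that fallers walk
less regularly. Default cohort shape is 35 fallers / 38 non-fallers, 60 s
at 100 Hz.

The default class separation is deliberately large so that end-to-end
checks separate reliably; passing them shows the pipeline recovers a
planted regularity difference, *not* that real fallers are this easy. Real
cohorts differ in ways the generator does not model: overlapping class
distributions, turns and pauses, sensor misorientation, non-gait segments,
and inter-subject variability beyond step frequency and jitter. Narrower
separations for robustness studies can be configured through the profile
functions.

Measured on this generator: step-timing jitter of {1, 4, 8}% degrades mean
V-axis step regularity strictly monotonically, and cadence recovery is
within 2% of ground truth at 2% jitter. The width of the dominant V
spectral peak grows with jitter up to roughly 8%, beyond which the peak
fragments and the width of the *most prominent* fragment saturates — a
property of prominence-ranked peak descriptors worth knowing when
interpreting wF1 on very irregular gait.

## Numerical choices and degenerate inputs

- Filter edges use odd-reflection padding of three low-edge periods, so
  zero-phase filtering sees no boundary step; a symmetric pulse's peak
  moves by at most one sample.
- Periodogram scaling satisfies the discrete Parseval identity
  `sum(P)·df = sum((xw)²)/sum(w²)` exactly; for stationary signals the
  integral approximates the signal mean square within a few percent.
- Ranking ties in ReliefF break by registry order (stable sort); neighbor
  ties by subject index.
- Constant feature columns min-max-scale to 0; constant axes are typed
  errors (`gaitfall_degenerate_signal`); an all-zero analysis band is a
  `gaitfall_degenerate_spectrum` error; subjects failing extraction are
  excluded from the cohort matrix with a logged reason rather than imputed.
- Every stochastic step (folds, MLP initialization and shuffling, cohort
  generation) derives its seed from one user-visible seed plus structural
  coordinates (fold index, grid cell), so results are independent of
  execution order.

## Problem sizes used in the shipped checks

The package's automated checks run on deliberately small instances chosen
to exercise every code path at interactive speed: single 60 s subjects for
signal-level properties; 10/10-subject cohorts for the full 40 × 36 sweep
structure at one hidden width; 20/20-subject cohorts over 10 generator
seeds with a reduced sweep (K ∈ {5, 10, 20}, N ∈ {5, 10, 20}, hidden ∈
{10, 50}) for end-to-end separation; and 40 × 30 planted-feature matrices
for selection-recovery checks. The acceptance script runs the full-size
73-subject default cohort with the complete K = 1..40 × N = 5..40 grid at
the 50-unit hidden width.

## Limitations

- **Whole-cohort feature selection is optimistic.** Following the reference
  study design, ReliefF sees the full cohort before cross-validation; only
  scaling and classifier training are fold-nested. On label-permuted
  cohorts (168 features, n = 40) the grid-selected pooled accuracy centers
  near 0.65–0.75 rather than 0.5 — a direct measurement of the selection
  bias this design admits. A fixed feature set without selection scores at
  chance under the same permutation, isolating the cause. Cross-validated
  accuracies from this pipeline should therefore be read as comparable to
  the reference methodology, not as unbiased generalization estimates;
  nesting the selection inside each fold would remove the bias at the cost
  of no longer producing one feature ranking per K.
- The 21-item time-domain and 32-item frequency-domain registries realize
  the stated feature categories at the exact published counts, but the
  original study's item-level list lives in its supplement; the registry
  functions are the single amendment point if an item differs.
- No resampling, orientation correction, turn removal, or non-walking
  segmentation: recordings are assumed to be clean straight-line walks.
- The synthetic generator is a signal model, not a biomechanical
  simulation; it validates the measurement chain, not clinical claims.
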