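---
title: "Methods: EEG emotion features and swarm-based feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG emotion features and swarm-based feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegselect)
```

## Overview

`eegselect` implements a complete subject-dependent pipeline for
valence–arousal emotion recognition from multi-channel EEG trials:
preprocessing, a multi-domain feature bank, wrapper feature selection by
particle swarm optimization (PSO) with a multi-stage linearly-decreasing
inertia weight (MLDW), and a leak-free nested cross-validation harness
around a linear support-vector machine. A deterministic synthetic EEG
generator with planted band-power effects makes every stage testable
without access to recorded data.

## Labels

Trials carry valence and arousal self-ratings on the 1–9 scale. Two label
schemes are supported: the four quadrant classes HAHV, HALV, LAHV, LALV
obtained by thresholding both ratings at 5 (a rating of exactly 5 counts as
High), coded 1–4; and a binary positive/negative scheme coded +1/−1. The
boundary convention follows the usual affective-corpus practice; ratings
exactly at threshold are rare in practice and the ≥ rule is applied
verbatim.

## Feature bank

For each trial, each of the C EEG channels contributes:

* **Six time-domain statistics** — mean, population standard deviation
  (1/N convention), mean absolute first and second differences, and both
  differences divided by the standard deviation. The normalized differences
  are defined as 0 for a constant channel rather than NaN.
* **Four band powers** — the one-sided Welch power spectral density
  (periodic Hann window, segments of `min(256, N)` samples, 50 % overlap)
  integrated over theta (4–8 Hz), alpha (8–14 Hz), beta (14–30 Hz) and
  gamma (30–50 Hz). Bands are half-open `[low, high)` so the four bands
  partition 4–50 Hz. The estimator is configurable; the Welch defaults are
  a pragmatic choice, validated in the tests by tone-localization and
  Parseval checks.
* **Four band differential entropies** — each band is isolated with a
  zero-phase 4th-order Butterworth filter, its variance estimated with the
  1/N convention, and the Gaussian closed form
  \(h = \tfrac{1}{2}\log(2\pi e\,\sigma^2)\) applied (natural log). The
  closed form rests on the band-limited signal being approximately
  Gaussian, which holds well for ongoing EEG. A zero-variance band yields
  the sentinel `-Inf`.
* **Ten wavelet features** — a five-level periodized db4 discrete wavelet
  transform; per detail level the energy \(\sum_k D_j(k)^2\) and the
  unnormalized log-energy entropy \(-\sum_k D_j(k)^2 \log D_j(k)^2\) with
  \(0\log 0 := 0\). Because the transform is orthonormal, coefficient
  energy equals signal energy, which the test suite checks to 1e-6 on 100
  random signals. Level band edges are derived from the actual sampling
  rate (at 128 Hz, D1 spans 32–64 Hz) and are carried in the column names;
  printed band tables that assume a different Nyquist are not reproduced.

Across hemispheres, each of the P montage pairs (by default the seven
mirrors FP1–FP2, F7–F8, F3–F4, T7–T8, C3–C4, P7–P8, P3–P4) contributes
**four rational-asymmetry ratios** `h(left)/h(right)`, one per band. A zero
denominator yields the sentinel `NaN`; downstream selection treats flagged
columns like any other (they are z-scored to 0 if constant).

The matrix therefore has \(F = 24C + 4P\) columns: 796 for a 32-channel
cap and 748 for a 30-EEG-channel cap with seven pairs. The 30-channel
layout reflects amplifier setups that dedicate four of their electrodes to
EOG; both layouts are first-class (`standard_montage()`). Column order is
family-major (statistics, band power, differential entropy, asymmetry,
wavelet), then channel in montage order, then band, and is fixed so that
selected-feature masks are portable; `attr(x, "family_slices")` exposes the
family index ranges.

## Preprocessing

The cleaning chain, per trial and per channel: a second-order IIR notch at
the power-line frequency (quality factor 30, applied forward–backward; the
design is exported by `notch_design()` so the realized response is
testable), a band-pass FIR (default 10th order, 0.1–70 Hz), time-domain
EOG regression, and polyphase resampling (default to 128 Hz, output length
`floor(n·target/fs)`).

Two honest caveats. First, a 10th-order FIR cannot realize a 0.1 Hz
transition at EEG sampling rates; the default order is kept for fidelity to
common practice, the order is configurable, and
`fir_bandpass_design()` returns the achieved coefficients so users can
inspect the response they actually get. The minimum-phase option reflects
zeros outside the unit circle, preserving the magnitude response while
minimizing group delay; with `bp_low = 0` the design degenerates to a
low-pass normalized to unity DC gain. Second, the EOG regression is
refitted per trial (ordinary least squares of every EEG channel on the EOG
channels, intercept included), which is the conservative choice when the
fitting window is not otherwise specified; the residual is exactly
uncorrelated with the regressors on the fitted segment and EOG channels
are dropped from the output.

Feature normalization is a z-score per column whose statistics are
**fitted on training folds only** and reapplied to test folds
(`normalize_features()` returns the statistics for exact reuse). This is
stricter than "normalize per participant" but is required for the nested
protocol to be leak-free. Columns with zero variance map to 0. Every
preprocessing stage can be disabled via `preproc_config(stages = ...)`,
since externally preprocessed corpora may already be filtered.

## PSO feature selection

Each particle is a real vector with one dimension per feature column.
Velocity and position follow the classic recursion

\[ V_i \leftarrow w V_i + C_1 R_1 (pbest_i - X_i) + C_2 R_2 (gbest - X_i),
\qquad X_i \leftarrow X_i + V_i , \]

with \(C_1 = C_2 = 2\), fresh uniform(0,1) draws per component, and
velocities clamped to ±0.4. A feature is selected when its position
component strictly exceeds the threshold \(\theta = 0.8\); an all-below
position selects its argmax so a mask is never empty. Positions initialize
uniformly in [0, 1] and are deliberately not clamped: with \(\theta =
0.8\), drift above 1 is what allows large fractions of the features to end
up selected. Fitness is the stratified inner 3-fold cross-validated error
of a linear SVM (cost 1) on the masked columns, evaluated on one fixed
fold assignment per run so that all masks are scored on identical splits.
Personal and global bests update under strict improvement — ties keep the
incumbent — which makes the best-so-far error non-increasing by
construction.

The inertia weight follows one of three laws over iterations
\(t = 0..t_{max}\) (defaults \(w_s = 0.9\), \(w_e = 0.4\),
\(t_{max} = 50\)):

* **constant** — \(w = w_s\);
* **LDW** — linear decrease, \(w = (w_s - w_e)(t_{max} - t)/t_{max} + w_e\);
* **MLDW** — three stages: linear decrease to a plateau \(w_m\) on
  \([0, t_1]\), hold on \((t_1, t_2]\), linear decrease to \(w_e\) on
  \((t_2, t_{max}]\). The law is continuous at both boundaries.

The named strategies `w1`–`w6` cover \(w_m \in \{0.8, 0.65, 0.5\}\) crossed
with \((t_1, t_2) \in \{(10, 40), (20, 30)\}\); `w0` is the LDW baseline.
The stage boundaries are defined at the reference budget of 50 iterations
and are rescaled proportionally for other budgets, so a shorter run keeps
the schedule's shape. A documented discrepancy in the method's published
pseudocode between a 10-iteration and a 50-iteration budget is resolved by
using a single configurable budget, default 50. The swarm size is not
specified by the original method; the default is 20.

One seeded random stream is consumed in a fixed documented order
(fold assignment, initial positions row by row, initial velocities, then
per iteration per particle \(R_1\) then \(R_2\)), making runs bitwise
reproducible; the test suite checks the whole trajectory against a
straight-line re-implementation at tiny scale.

As a filter baseline, `relief_select()` implements classic Relief: for
each instance the nearest same-class hit and nearest other-class miss
(Euclidean distance on range-scaled features) contribute the per-feature
miss-minus-hit margin; the top `floor(keep_fraction · F)` features by
weight are kept (374 of 748 at the default 0.5), with ties broken by
column index for reproducibility.

## Nested evaluation

`nested_crossval()` runs stratified outer k-fold (default 5) evaluation in
which, per fold, normalization statistics and the feature mask are fitted
on the training folds only, then frozen before the held-out fold is
touched. The classifier is a linear soft-margin SVM with cost 1 and
one-vs-one multiclass decomposition (the defaults of the underlying libsvm
implementation). Stratified folding keeps per-class counts across folds
within one of each other; the spec of the protocol said only "divided into
five samples", and stratification is the choice that preserves class
balance for quadrant-labeled data. `compare_selectors()` reproduces the
strategies-by-budgets comparison layout by running each strategy once at
the largest budget and scoring the best-so-far mask at each intermediate
budget from the selection trace.

## Synthetic EEG generator

`generate_synthetic_trials()` synthesizes each trial/channel in the
frequency domain: complex Gaussian coefficients shaped by
\(f^{-\alpha/2}\) (default \(\alpha = 1\), the typical 1/f EEG spectrum),
scaled to a background RMS of 10 µV, with class-specific multiplicative
power factors applied directly to the spectral bins of chosen bands on
chosen channels. Because effects multiply the spectrum, the planted
between-class band-power ratio equals the configured factor exactly in
expectation, making the generator a ground-truth oracle for the feature
extractor. Defaults emulate the common affective-corpus layout — 20 trials
per class, 32 channels, 128 Hz, 60 s — with one band effect of factor 2
per class on the first eight channels; a 30-channel/250 Hz layout is
available for the online-amplifier geometry. Ratings are drawn uniformly
in the half-interval matching the trial's class ([5, 9] High side,
[1, 5) Low side). `inject_eog()` adds a low-frequency blink-like source to
frontal channels with recorded mixing coefficients and appends the source
as an explicit EOG channel, so artifact removal can be validated against
ground truth.

What the generator does *not* emulate: event-related potentials,
non-stationarity, inter-channel correlation structure beyond the planted
effects, electrode drift, or muscle artifacts. Passing tests on synthetic
data therefore demonstrate the pipeline's correctness and the selector's
behaviour under known ground truth — not recognition accuracy on recorded
EEG.

## Numerical choices and degenerate inputs

* Standard deviation uses 1/N throughout the statistical features;
  normalized differences at zero variance are 0.
* Differential entropy of a zero-variance band is `-Inf`; asymmetry with a
  zero denominator is `NaN`. Both are sentinels, not errors.
* The periodized DWT extends odd-length levels by wrapping one sample;
  test signals use lengths divisible by \(2^{levels}\) where exact energy
  conservation is asserted.
* Interchange I/O (raw little-endian doubles + JSON sidecar) round-trips
  exactly; EDF round-trips are limited by its 16-bit quantization, and the
  physical-range fields are widened slightly so the 6-significant-digit
  header format still brackets the data.
* `stratified_folds` errors when any class has fewer members than folds;
  single-class training sets are an explicit error.
* All randomness is funneled through a locally seeded RNG that restores
  the caller's RNG state (`with_seed`), and the pipeline fans one global
  seed out to per-stage child seeds deterministically.

## Test problem sizes

The suite exercises every stage at sizes chosen to give sharp oracles at
desk scale: feature-count contracts on full 32- and 30-channel
extractions of short (4 s) trials; planted band-power recovery at 20 and
50 trials per class; the selector's trajectory oracle at 4 features, 2
particles, 2 iterations; recall and accuracy comparisons on the planted
feature design (5 informative columns of standardized shift 1.0 among
100, 60 trials) over 10 fixed seeds with the selector at its default
scale (50 iterations, 20 particles).

## Known limitations

* Wrapper selection at very small sample sizes overfits its inner
  cross-validation: the fitness is evaluated on the order of a thousand
  times per run against one fixed split, so the returned best mask is
  partly fitted to that split's noise. On the planted design above, the
  suite's Monte-Carlo comparison finds informative-column recall clearly
  above a size-matched random baseline, yet nested accuracy with
  selection does not exceed the no-selection condition — even the oracle
  informative-only mask beats all-features by only a few points there.
  The corresponding acceptance assertion is kept at its stated condition
  and documents this behaviour; gains like those reported on real
  recordings depend on feature redundancy that the independent-noise
  design deliberately lacks.
* The 10th-order band-pass FIR is a faithful but weak realization of a
  0.1–70 Hz specification; raise `fir_order` for a meaningful high-pass
  edge.
* Relief here is the classic two-class/nearest-neighbour form extended to
  multiclass via the nearest miss over all other classes, not ReliefF
  with k neighbours and prior weighting.
* EDF support covers the subset of the format the package writes (one
  data record per trial, identical sampling across channels); it is not a
  general-purpose EDF reader.
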