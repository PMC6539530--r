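---
title: "Methods: from wearable ear-EEG/ECG to a stress classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wearable ear-EEG/ECG to a stress classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Behind-the-ear wearables record two EEG channels (left/right mastoid
against a forehead reference) and, by differencing the two active
electrodes, a single head ECG. Signals are digitized at 250 Hz in
microvolts. The head ECG is tiny — R-peaks of roughly 25 uV, versus
~0.5 mV for a standard limb lead — so QRS detection has to work at an
order of magnitude less signal than usual. Laboratory stress protocols
alternate stressors and rest in four 6-minute stages: a Stroop color-word
test (S1), rest (R1), mental arithmetic (S2), rest (R2). The analysis
question is whether heart-rate-variability (HRV) and EEG features
separate the stressor stages from rest, and how well a linear classifier
does on the combined feature set.

`earstress` implements the full chain: R-peak detection, six HRV
features, EEG cleaning and eight band-power/asymmetry features,
per-feature ANOVA across stages, and stress-vs-rest classification with a
linear SVM under stratified five-fold cross-validation. Because no public
recordings of this kind exist, the package also ships synthetic signal
and cohort generators with exact ground truth; every stage of the
pipeline is validated against those.

## R-peak detection

`detect_r_peaks()` is a Pan–Tompkins detector: band-pass 5–15 Hz, a
five-point derivative, squaring, 150 ms moving-window integration, and
dual adaptive thresholds on the integrated and filtered signals with
running signal/noise peak estimates (exponential updates 0.125 for
regular detections, 0.25 for search-back detections; the decision
threshold sits a quarter of the way from the noise level to the signal
level). A 200 ms refractory period suppresses double detections; a
candidate within 360 ms of the previous QRS whose maximal slope is less
than half of the previous QRS slope is discarded as a T-wave; and when
the interval since the last QRS exceeds 1.66 times the running 8-beat RR
average, the skipped candidates are rescanned at half threshold
(search-back). All numeric constants are exposed as arguments.

Two choices differ from a streaming implementation, both because this is
offline analysis:

* **Zero-phase filtering.** The detection band-pass runs forward and
  backward, and the derivative and integration stages are centered, so
  no group-delay bookkeeping is needed.
* **Fiducial refinement.** The moving-window-integrated signal is a
  plateau around each QRS and localizes poorly, so each accepted
  detection is first anchored at the filtered-signal peak within the
  integration window and then refined to the raw-signal extremum (by
  magnitude, so inverted QRS needs no polarity flag) within ±40 ms. At
  250 Hz this pins noiseless synthetic peaks exactly and keeps interval
  jitter at head-ECG noise levels below one sample almost everywhere.

## HRV features

From intervals $RR_1 \dots RR_N$ (ms):

$$\mathrm{mRR} = \tfrac{1}{N}\sum_i RR_i,\qquad
\mathrm{SDRR} = \sqrt{\tfrac{1}{N-1}\sum_i (RR_i - \mathrm{mRR})^2},\qquad
\mathrm{RMSSD} = \sqrt{\tfrac{1}{N-1}\sum_{i=1}^{N-1} (RR_{i+1}-RR_i)^2}.$$

For the frequency domain the interval series is linearly interpolated
and resampled at 2 Hz (each interval anchored at the beat that closes
it), mean-removed, and a single periodogram of the whole stage is taken
— one 6-minute window per stage. LF power integrates the density over
[0.04, 0.15) Hz and HF over [0.15, 0.4] Hz. Normalized powers are
percentages of total power, and the ratio is reported scaled:

$$\mathrm{nLF} = 100\,\frac{P_{LF}}{P_{tot}},\qquad
\mathrm{nHF} = 100\,\frac{P_{HF}}{P_{tot}},\qquad
\mathrm{LF/HF} = 100\,\frac{\mathrm{nLF}}{\mathrm{nHF}}.$$

Two conventions deserve justification:

* **Total power** integrates over (0, 1] Hz with DC excluded but the
  very-low-frequency region below 0.04 Hz included. Excluding DC is
  necessary for the percentages to mean anything; including VLF is
  consistent with reference cohorts in which nLF + nHF is around 20%,
  far below what an LF+HF-only denominator would give.
* **The ×100 ratio scale.** nLF/nHF is order 1; published group values
  for this ratio in comparable cohorts are order 100. We therefore
  report LF/HF as $100\cdot\mathrm{nLF}/\mathrm{nHF}$. Note that a group
  mean of per-subject ratios is not the ratio of group means, so
  cross-checking the ratio against published normalized-power means
  reproduces the magnitude, not the exact printed value.

## EEG features

Both EEG channels are band-pass filtered to 1–35 Hz (zero-phase
Butterworth, order 4 per direction). Eye movements are the dominant
artifact at these electrode sites; any 1 s epoch in which either channel
exceeds 100 uV in absolute value is discarded, and both channels share
one mask because the asymmetry features need paired data.

Band powers come from a Welch estimate restricted to clean data: Hann
windows spanning 8 consecutive clean epochs (8 s, 0.125 Hz resolution),
stepped one epoch at a time, mean-removed, tapered, averaged. Windows
never bridge a rejected epoch — splicing across gaps would turn the
discontinuities into broadband leakage. The window length matters: 1 s
Hann windows have a ±2 Hz main lobe, which visibly bleeds adjacent bands
into each other (a 3:1 prescribed alpha ratio came out as an asymmetry
of ~39 instead of 50 in our validation); 8 s windows recover prescribed
band variances to within ~5%, the residual being the filter shoulder at
the band edges (the 1 Hz high-pass grazes delta, the 35 Hz low-pass
grazes beta — both channels equally, so asymmetries are unaffected).

Bands are delta [1, 4), theta [4, 8), alpha [8, 13), beta [13, 30) Hz
(delta/theta edges are the conventional clinical choices). With
per-channel totals over 1–35 Hz:

$$\mathrm{nLAP} = 100\,\frac{P_{\alpha,L}}{P_{tot,L}} \quad(\text{likewise nRAP, nLBP, nRBP}),$$

and for each band $b$ the asymmetry on *normalized* band powers,
reported on a −100…100 scale:

$$\mathrm{xPA}_b = 100\,\frac{\tilde P_{b,R} - \tilde P_{b,L}}{\tilde P_{b,R} + \tilde P_{b,L}},
\qquad \tilde P_{b,\cdot} = P_{b,\cdot}/P_{tot,\cdot}.$$

Using normalized rather than absolute powers makes the asymmetries
invariant to inter-channel gain differences, which unmatched electrode
impedances otherwise inject directly into the feature. When the two
channel totals are equal the normalized and absolute versions coincide.

## Statistics and classification

`anova_by_feature()` runs a one-way ANOVA per feature across the four
stages, then the four pairwise Welch t-tests contrasting each stressor
with each rest stage. A repeated-measures design would also be
defensible for within-subject protocols; the between-stage one-way
layout is the simpler default and is what the package implements.

`rank_features()` orders features by the absolute difference between the
stress and rest class means on z-scored values (z-scoring makes the
criterion scale-free; the features span three orders of magnitude). The
three standard models use the published four-feature selections: EEG =
(APA, nLAP, nRAP, BPA), HRV = (LF/HF, nHF, nLF, mRR), EEG+HRV = (nLAP,
APA, nHF, LF/HF).

`crossvalidate_svm()` partitions the subject-stage rows into five
stratified folds under a seed. Per fold, z-scoring parameters and the
linear SVM (cost 1; both exposed) are fit on the training folds only —
computing the standardization on all data first would leak test
information. Sensitivity is stress recall, specificity rest recall, AUC
comes from the decision values, and the fold ROC curves are vertically
averaged (mean TPR on a 0.01-spaced FPR grid, with an explicit (0,0)
origin). Rows are the sampling unit by default, matching a design in
which all samples are pooled before the random split; `group_by_subject
= TRUE` provides the stricter subject-grouped alternative, since
row-level folding lets a subject appear on both sides of a split.

## What the generators emulate — and what they do not

* `generate_rr_series()` builds intervals as a mean plus LF and HF
  sinusoids plus Gaussian jitter, applied directly to the intervals.
  This puts the modulation energy at exactly the prescribed frequencies
  (the point of the ground truth); it is not an integral-pulse-frequency
  model and does not emulate respiratory sinus arrhythmia mechanics.
* `generate_ecg()` renders a biphasic Mexican-hat QRS (default 0.1 s
  wavelet support) at each beat time, snapped to the sample grid, plus
  white noise and an optional T-wave bump. Real head ECG has richer
  morphology and colored noise; the template is deliberately the
  simplest shape with one sharp, unambiguous R maximum.
* `generate_eeg()` sums per-band Gaussian noise synthesized in the
  frequency domain (ideal brick-wall bands) and scaled to the prescribed
  variance exactly, plus 0.5 s half-sine EOG deflections (300 uV
  default) added to both channels. Real EEG has 1/f structure,
  nonstationarity and asymmetric artifact topographies; none of that is
  claimed.
* `generate_feature_cohort()` draws features independently from
  per-condition Gaussians parameterized by a published 14-subject
  reference cohort (`stress_cohort_params()`). Independence is an
  assumption forced by the absence of published covariances; real
  features correlate (nLF and LF/HF strongly so), which classifier
  results on synthetic cohorts inherit as an optimistic simplification.

Passing tests on these generators therefore demonstrate correctness of
the signal processing and honest behavior of the statistics under known
ground truth — not field performance on real recordings.

## Numerical choices and degenerate inputs

* Stage slicing uses half-open `[start, start+duration)` windows at
  sample resolution.
* Tachograms shorter than 64 samples, fewer than 2 detected beats,
  fewer than 8 clean epochs, or an all-rejected mask raise explicit
  errors rather than returning silent NAs.
* Zero HF power makes LF/HF undefined: reported `NA` with a warning.
  A band with zero power in both channels makes its asymmetry undefined:
  likewise `NA` with a warning. Zero within-group variance makes the
  ANOVA F infinite (or NaN when between-group variance is also zero),
  flagged in the result.
* Ties in feature ranking break in candidate-list order; fold
  re-draws happen only if a training split lacks a class, with a
  warning.
* The EDF writer re-parses its own printed physical bounds before
  quantizing, so a write/read cycle is exact to the 16-bit step.

## Problem sizes used in validation

The test-suite simulations use 6-minute single-stage records for
detector and artifact checks, 2-minute records for EEG recovery,
14-subject cohorts (the reference cohort's size) for classification and
power analyses — 20 replicate cohorts for accuracy floors, 50 for null
calibration, 100 for contrast power — and 60 s stages for end-to-end
pipeline runs. These sizes give stable pass/fail behavior at fixed
seeds while keeping the full suite fast.

## Known limitations

Ectopic beats are not corrected and nonlinear HRV indices are out of
scope. EOG handling is rejection, not correction (no ICA/regression).
The classifier is deliberately a single linear SVM; no hyperparameter
search is performed. Whether row-level or subject-grouped folding is the
right generalization claim depends on the deployment question; both are
provided, and the default follows the pooled-sample design.
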