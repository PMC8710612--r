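---
title: "Assessing loneliness from speech: models, parameters and design choices"
author: "lonevox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing loneliness from speech: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Loneliness in older adults is usually measured with the 20-item UCLA
Loneliness Scale (total score 20–80, higher = lonelier). Because speech
production runs through motor, cognitive and physiological systems that
chronic psychological stress can perturb, speech recorded in everyday
settings is a candidate passive marker of loneliness. `lonevox`
implements a complete desk-scale version of that idea: per-question speech
recordings and transcripts go in; a fixed 160-dimensional feature vector,
a correlation screen against the UCLA score, and cross-validated
regression/classification performance come out. Because clinical
recordings of this kind are not publicly distributable, the package ships
a synthetic-cohort generator that reproduces the study conditions end to
end, so every stage is testable.

## The feature vector

Each participant answers eight daily-life questions. Per response the
package computes:

* **Acoustic (16 per response, 128 per session).** First and second
  formant (F1, F2) from LPC polynomial roots (autocorrelation method,
  Levinson–Durbin, order `2 + rate/1000`), and the per-coefficient
  population variances of the first-order deltas of MFCC coefficients
  1–14. F2 tracks tongue frontness and falls with flattened articulation;
  low ΔMFCC variance is the signature of monotone, spectrally static
  speech.
* **Prosodic (2 per response, 16 per session).** Pitch variation — the
  population SD of frame-level F0 over voiced frames — and pause
  duration, the summed internal silences between the first and last
  voiced interval.
* **Linguistic (16 per session).** Positive and negative word counts on
  the four questions expected to elicit sentiment (questions 3, 6, 7, 8:
  childhood activity, earthquake plan, travel plan, traditional event),
  and the filler-word proportion on all eight. Dictionaries are plain
  files (TSV lexicon, one-filler-per-line list); the tokenizer is
  pluggable so a real morphological analyzer can replace the default
  whitespace+lowercase rule.

All frame-level aggregations use population (not sample) variance/SD; the
choice is fixed once, here, and used consistently.

## Segmentation and the DSP parameters that matter

The original analysis delegated voice-activity detection to a cloud ASR
service; that is neither reproducible nor dependency-free, so segmentation
here is energy-based: 25 ms analysis windows on a 10 ms tile grid, a
voicing threshold of −30 dB relative to the loudest frame, and a 0.2 s
minimum segment (shorter runs are absorbed, shortest first). The
segmentation always tiles the response exactly, which the test suite
asserts on random signals.

Key defaults (all overridable through `speechConfig()`):

| parameter | default | why |
|---|---|---|
| analysis rate | 16 kHz | retains the 90–4000 Hz formant band; inputs are resampled |
| MFCC frame/hop | 25/10 ms, Hann, 512-pt FFT, 26 mel filters | conventional speech framing |
| MFCC coefficients | 1–14 (c0 excluded) | c0 is loudness, not spectral shape; `mfcc_include_c0` switches |
| Δ half-window | 2 frames | standard regression delta |
| F0 band / frames | 60–400 Hz, 40/20 ms, voicing threshold 0.5 | ≥2 periods of the lowest F0 per frame |
| LPC order | 18 at 16 kHz | `2 + rate/1000` rule |
| formant gates | 90–4000 Hz, bandwidth < 400 Hz | plausible vocal-tract resonances |
| pre-emphasis | 0.5 | see below |

Two numerical choices deserve a note. First, **pre-emphasis**: the
classical 0.97 assumes a −12 dB/oct glottal roll-off. On flat-spectrum
excitation (the synthetic vowels used for validation, and the generator's
pulse train) 0.97 over-whitens and biases a 300 Hz F1 upward by ~19%; at
0.5 the median recovery error across a 300–800 × 900–2400 Hz grid is
0.5%. Second, **F0 peak refinement**: the autocorrelation peak is
parabolically interpolated, which keeps pulse-train recovery within 2 Hz
up to 350 Hz where the raw lag grid alone would quantize to ~4 Hz.

Pitch variation and pause duration are not operationally defined in the
source description; the package fixes them as the population SD of voiced
frame F0 and the total *internal* silence (leading/trailing silence
excluded), both stated in the function documentation and configurable at
the call sites.

## Screening and confound adjustment

Every feature is tested against the UCLA score with Spearman's rank
correlation; p-values use the t approximation on n−2 degrees of freedom
(an exact enumeration mode exists for n ≤ 8). Screening is deliberately
unadjusted for multiplicity, mirroring the exploratory protocol; a
Benjamini–Hochberg column is available but off by default. "Controlling
for age and sex" is implemented as rank-based partial correlation —
rank-transform, residualize on an intercept plus confounders by least
squares, correlate residuals on n−2−k degrees of freedom — since the
original method is unstated and stratification is infeasible at n=57.
Post-hoc power uses the Fisher-z normal approximation,
`power = pnorm(sqrt(n-3)*|atanh(rho)| - qnorm(1-alpha/2))`.

## Evaluation protocol

The cutoff for the high-loneliness class is the sample mean plus one
sample SD, rounded (37.0 + 8.6 → 46; scores ≥ cutoff are "high"). The
cross-validation protocol per iteration and fold:

1. impute missing features with training-fold medians;
2. z-score features on training moments (kNN/SVM; forests are invariant);
3. reduce the 128 acoustic features to the top 16 by training-fold
   Spearman |ρ| with the score, giving the fixed 48-candidate set
   (16 acoustic + 16 prosodic + 16 linguistic);
4. sequential forward selection against a pooled inner-CV objective
   (R² for regression, accuracy for classification), stopping at no
   improvement or 12 features;
5. optional grid search over the model hyperparameters on the training
   rows;
6. fit, predict the held-out fold.

Metrics (R², explained variance `1 − Var(resid)/Var(y)`, MAE, RMSE;
accuracy/sensitivity/specificity/F1 with pooled confusion counts) are
computed per iteration over the pooled test predictions, and reported as
the mean with a 95% t-interval over the 20 iteration values. Stratified
folds keep the ~10/57 positive class represented in every training split.
Everything derives from one root seed, so reports are bit-identical across
reruns.

Design choices made where the protocol was genuinely open: the SFS
stopping rule (no-improvement, capped at 12 — bracketing the reported
8–10-feature final models; a fixed-size mode via `min_features` exists);
inner CV with 5 folds (3 proved too noisy a selector at ~51 training
rows); per-fold grid search as the leakage-safe reading of "we performed
a grid search"; and the SVM hyperparameter set including the kernel
(linear/radial), because kernel choice was explicitly part of the original
search — on small cohorts the linear kernel is the stronger default, so it
is the package default while grid search can still pick the RBF.

## The synthetic cohort

`cohortSpec()` fixes the study conditions: 57 participants, UCLA scores ~
Normal(37.0, 8.6) truncated to [20, 80] and rounded, ages 62–81, balanced
sex, eight responses each. Six latent effect families carry the reported
association directions: pitch variation (−), pause duration (+), F2 (−),
spectral modulation depth driving ΔMFCC variance (−), positive-word rate
(−), filler rate (+); the negative-word rate is deliberately null.
`calibrateEffects()` sets each latent's link slope from the
bivariate-normal rank relation `s = 2 sin(pi * tau / 6)` and verifies it
on a 2000-participant pilot to ±0.03. The default target is |ρ| = 0.38 —
the upper middle of the reported 0.26–0.41 significance band — chosen so
that after synthesis and extraction the strongest extracted feature per
family still lands inside the band at n = 57.

Audio is source-filter synthesized: a glottal pulse train (pitch redrawn
per 100 ms from N(f0_mean, f0_sd)) through two resonators (F1 ≈ 550 Hz,
F2 participant-specific), with slow random modulation of the resonator
frequencies and of a one-pole spectral tilt, scaled by the participant's
modulation depth. A subtlety forced this design: pure *amplitude*
modulation is invisible to MFCC coefficients 1–14 (a gain change adds a
constant to all log mel energies, which the DCT maps entirely into the
excluded c0), so spectral dynamism — not loudness dynamism — must carry
the ΔMFCC-variance effect. Pauses are inserted as internal silences whose
total tracks the participant's latent pause fraction of the *typical*
response length, so that random per-response durations do not drown the
effect. Transcripts are i.i.d. draws over filler/positive/negative/neutral
pseudo-words from the bundled toy dictionaries, at 2.8 tokens/s.

What the generator does **not** emulate: phones and phonotactics, prosodic
phrasing, ASR errors, channel/room acoustics, and any dependence between
families beyond their common link to the score. Passing tests therefore
demonstrate that the pipeline recovers known monotone effects through a
real DSP chain — not that the specific cross-validated numbers transfer
to clinical recordings.

## Problem sizes used by the tests and the acceptance script

Responses default to 4–12 s (a desk-scale compression of the reported
4.2–75.4 s range; `duration_range = c(4.2, 75.4)` restores it), which
makes a full 57-participant extraction a ~2-minute computation. The test
suite evaluates the cross-validated models at 2 iterations of 10-fold CV;
the acceptance script runs the regression models at the full 20 iterations
and the classification model at 3. The
calibration invariant is verified on latent parameters at pilot size
2000; verifying extracted-feature calibration at n = 500 would require
synthesizing 4000 responses and is deliberately out of test scope.

## Known limitations

* At n = 57 with six |ρ| ≈ 0.38 families, the out-of-sample ceiling of
  the synthetic cohort is modest (a leave-one-out linear model on the six
  true family means reaches R² ≈ 0.26 on a typical draw); cross-validated
  R² values are accordingly small and iteration-noisy, and only the
  *ordering* (combined features ≥ single-type features) is a stable
  property. The original study's absolute numbers depend on its
  unreleased recordings.
* Classification at the mean+1SD cutoff separates poorly under these
  effect sizes; sensitivity is low at any reasonable operating point.
* The energy-based VAD assumes a quiet recording environment, as in the
  original tablet sessions; it is not noise-robust by design.
* Formant estimation assumes adult vocal tracts and resolvable F1/F2
  below 4 kHz; responses whose frames never yield two candidates are
  recorded as missing and median-imputed at modeling time.
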