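---
title: "Quantifying swallowing sounds: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying swallowing sounds: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swallowsound)
```

## The problem

Swallowing dysfunction in neurodegenerative disease — amyotrophic lateral
sclerosis (ALS) in particular — raises the risk of aspiration pneumonia, and
the gold-standard assessments (videofluoroscopy, endoscopy) are not suited to
frequent or home-based screening. Cervical auscultation offers a non-invasive
alternative: when a bolus of water passes the open esophageal entrance it
produces short, transient, high-frequency acoustic events with the character
of *fine crackles*. As swallowing function declines, these inflow sounds
fade. `swallowsound` quantifies them from a mono WAV recording of an
electronic stethoscope placed at the top of the sternum during repeated
small-volume (3 mL) water swallows.

## The pipeline

1. **Edge trimming.** The stethoscope's contact sensor delimits the
   auscultation; 0.2 s at each edge is excluded (`trim_auscultation()`).
   Trimming is performed in whole samples, `round(edge_s * rate)` per side,
   so section lengths are exact and testable.
2. **Framing.** Frames are placed every 12 ms (`make_grid()`). The analysis
   window is 24 ms — twice the hop — because cepstral features are unstable
   on very short windows. Both are configuration keys.
3. **Features.** Each frame yields a 148-dimension vector `x`
   (`extract_raw_features()`), min–max normalized to \[-1, 1\]
   (`fit_normalizer()` / `apply_normalizer()`).
4. **Frame classification.** A linear score `y = sum(a_i * x_i)` is compared
   with a learned threshold (`score_frames()`); the coefficients and the
   threshold come from boosting (`train_crackle_model()`).
5. **Indices.** The per-second fine-crackle quantitative value (FCQV) is the
   fraction of frames per second classified as target sound
   (`compute_fcqv()`); the per-trial index is the same fraction over the
   whole auscultation section (`compute_trial_index()`); the participant's
   swallowing sound index is the maximum over trials
   (`aggregate_trials()`). A simple discriminator flags any second whose
   FCQV exceeds a threshold (`detect_swallow()`).

## The feature layout

The deployed discriminant is a linear form over exactly 148 normalized
features built from frequency analysis, local variance, cepstrum analysis
and liftering. The published description names the techniques but not the
individual features, so the layout here is this package's own documented
default (`default_feature_layout()`), serialized with every model:

| block | count | content |
|---|---|---|
| `mel_logE_*` | 40 | log-energies on a mel-spaced triangular filter bank, 50 Hz–20 kHz (capped below Nyquist), floored at −80 dB re full scale |
| `ceps_*` | 24 | cepstral coefficients c1–c24 (DCT-II of the log-mel spectrum) with a low-time lifter (cutoff 24, configurable) |
| `dceps_*` | 24 | within-window delta-cepstra: second half-window minus first |
| `bandvar_*` | 40 | local variance of the log band energy across 4 sub-blocks of the window |
| scalars | 20 | zero-crossing rate, spectral centroid/bandwidth, rolloff at 5 quantiles, within-window flux, flatness, crest factor, frame log-RMS, envelope skewness/kurtosis, 6 high/low band-energy log-ratios (splits 250–8000 Hz) |

Choices worth noting:

* **Min–max normalization with clipping**, not z-scoring: the feature
  contract is literally `-1 <= x <= 1`, which only a bounded map guarantees.
  A feature constant in training maps to 0.
* **Spectral floor** at −80 dB keeps silence finite; a silent section maps
  to a fixed feature vector (energies at the floor, variances and
  descriptors at 0).
* **Within-window deltas** only: no temporal context crosses frame
  boundaries, so the feature matrix is strictly row-local and shift-covariant
  (shifting the input by one hop shifts rows by one).
* The canonical rate is 44.1 kHz — it covers the stethoscope's stated
  20 kHz analog upper band edge. The stored-file rate is not documented
  anywhere, so this is a package choice, not a recorded fact; the filter
  bank caps itself below Nyquist at other rates.

## Training: boosting with a linear deployed form

The method is described as AdaBoost-trained, yet deployed as a strictly
linear score. `train_crackle_model()` honors both:

1. Discrete AdaBoost over depth-1 decision stumps, each thresholding a
   single normalized feature. Initial example weights are balanced per
   class, because crackle frames are a small minority of any recording.
2. The boosted additive margin is then projected by least squares onto the
   linear form `y = sum(a_i * x_i)` over the training frames. The
   projection is restricted to the features the stumps actually vote on;
   every other coefficient is exactly 0. An intercept is carried during the
   fit and absorbed into the decision threshold, so deployment needs only
   `a` and the threshold.
3. The threshold is chosen to maximize balanced accuracy on the training
   frames (`choose_threshold()`). Candidates are midpoints between adjacent
   distinct scores; ties on balanced accuracy resolve to the middle of the
   tied range, which makes the choice equivariant under constant shifts of
   the scores. Whether the original threshold was tuned on training or
   held-out data is not documented; training-set balanced accuracy is this
   package's declared choice, recorded in `training_meta`.

Training is deterministic: stump search has no randomness and ties break to
the lowest feature index, so permuting clip order changes nothing. The model
serializes to a single JSON document with 17 significant digits, which
round-trips IEEE doubles exactly — reloading a model reproduces scores
bitwise.

Clip-level labels (a whole clip marked positive) are broadcast to all of the
clip's frames; frame-level label tracks are preferred and are what the
synthetic generator emits.

## Index scales

The index formula multiplies the frame fraction by 100, yet published
summary values (e.g. a patient mean near 0.21 and a healthy mean near 0.37)
are on the unit scale. Both scales are therefore always computed;
`index_fraction` is the reported default and `index_percent` is emitted
alongside. A trailing partial second contributes its actual frame count to
the FCQV series rather than being discarded — short swallow recordings would
otherwise lose data. An alternative reading of the trial index (maximum
per-second FCQV instead of the whole-section fraction) can be obtained from
the FCQV series directly.

## What the synthetic generator does and does not emulate

No teacher clips or patient recordings are published, so all testing runs on
synthetic data.

* **Crackle bursts** are exponentially damped sinusoids (default 650 Hz
  carrier, 4 ms decay, 10 ms duration) — the standard parsimonious
  surrogate for a transient fine crackle.
* **Recordings** are white (optionally 1/f) Gaussian noise with bursts at
  homogeneous Poisson times inside a swallow window; the burst gain is set
  analytically so the realized burst-support SNR equals the target exactly
  (10 dB by default). Ground-truth labels mark every frame that overlaps a
  burst. The swallow window must sit inside the trimmed region so labels
  survive trimming.
* **Teacher sets** default to 50 clips, half positive, mirroring the size
  of the original teacher data.
* **Cohorts** draw the clinical covariates of an ALS background table (age
  64 ± 11.8 y, ALSFRS-R total around 39 with range 18–47, bulbar sub-score
  near 10.5 of 12, %VC 80.5 ± 20.4, tongue pressure 27.6 ± 16.2 kPa, MASA
  totals near ceiling) as rounded, range-clipped normals, and generate the
  index from a planted linear model (default: 0.006 per ALSFRS-R point,
  residual SD 0.04, intercept set so the mean index is near 0.21).

What passing tests on these data show: the pipeline detects damped-sinusoid
transients in stationary Gaussian noise at 10 dB SNR and preserves burst
density ordering; the statistics layer recovers planted linear effects with
nominal CI coverage. What they do not show: performance on real cervical
auscultation, where noise is nonstationary (breathing, motion artifacts,
voice), crackle morphology varies, and the stethoscope transfer function
shapes the spectrum. Clinical summary values (group means, AUC 0.792,
cutoff 0.228) depend on unpublished patient data and are documentation
context only, never test expectations.

## Statistics layer

* Group comparison: two-sided Welch t-test by default (Student's by
  option), chi-square for categorical factors.
* Two-step screening: univariate linear models of the index on each factor;
  factors with p < 0.05 — plus age, always — proceed to age-adjusted models,
  one per factor (`index ~ factor + age`), matching a per-row multivariate
  table at the published cohort size (n = 24). The original text says
  "multiple logistic analysis", but the published per-factor coefficients
  (0.006 per ALSFRS-R point on a unit-scale index) are linear-regression
  magnitudes; the linear model is therefore the implementation, with a
  logistic variant (outcome = index below a cutoff) behind a flag.
* ROC: empirical Mann–Whitney AUC with a Youden-J cutoff over observed
  index values; ties resolve to the lower cutoff (favoring sensitivity),
  and the direction — low index predicts impairment — is auto-detected and
  reported. The impaired class defaults to an ALSFRS-R bulbar sub-score
  below full marks (12), the reading taken of the published outcome
  definition; a total-score outcome is available in `cmd_stats()`.
* Sample size: smallest total n (two equal groups) whose two-sided t-test
  power reaches the target, evaluated with `stats::power.t.test()`. The
  planning inputs Δ = 0.08, SD = 0.06, α = 0.05, power = 0.80 give 10 per
  group, 20 in total.

## Numerical choices and degenerate inputs

* FFTs are zero-padded to the next power of two; frames are Hann-tapered.
* Feature extraction is processed in column chunks (default 2048 frames)
  to bound memory; identical input and configuration give bitwise-identical
  matrices. Different chunk sizes regroup BLAS matrix products and may
  differ in the last ulp, which is why chunk size is part of the
  configuration rather than a free parameter.
* Silence, zero-variance features, all-equal score distributions and
  single-class label sets are all either mapped to defined values (0, the
  floor, a flagged degenerate threshold) or rejected with a specific error.
* Boosting stops early when a stump achieves (near-)zero weighted error or
  when no stump beats chance.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on synthetic data at
the default 44.1 kHz rate: a 50-clip teacher set (0.5-s clips) for training,
20 independent clips (~800 frames) for held-out frame accuracy, a 10-level
burst-density sweep of three 6-s trials per level with a 4-s swallow
window — long enough that the realized Poisson burst count at each level is
representative of its nominal density, which is what a monotonicity check
of the index against density presumes — and 100 replicate cohorts of
n = 500 for CI coverage. These sizes are the package's own choices; larger
runs only narrow the Monte-Carlo error of the same quantities.

## Known limitations

* The 148-feature layout is a reconstruction of the named technique
  families, not the original (unpublished) feature list; likewise the
  stump-boosting-plus-projection training is a declared interpretation of
  "AdaBoost with a linear deployed form". Coefficients are therefore not
  comparable to the original device's.
* The synthetic crackle model ignores bolus-size effects, laryngeal
  elevation sounds and the stethoscope transfer function.
* WAV support covers mono PCM16/PCM24/float32 (multi-channel files can be
  averaged down); other encodings are rejected.
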