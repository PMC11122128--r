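---
title: "SVD-based temporal eye signals: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SVD-based temporal eye signals: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyesvd)
```

## The problem

During screen-based learning, attention drifts ("mind-wandering").
Probe-caught protocols label short video windows as *Focus* or *non-Focus*,
and the practical question is whether those states can be predicted from a
webcam alone. Eye behaviour is the strongest cue: blinks and eyelid
aperture on one hand, pupil fixations and saccades on the other. The
eye-aspect-ratio (EAR) baseline captures only the eyelid; gaze trackers
capture only the pupil and are computationally heavy. This package
implements a middle path: a single one-dimensional temporal signal, derived
from the whole cropped eye region by singular value decomposition, that
reflects both kinds of movement using nothing but eye landmarks.

## The signal model

A cropped eye sequence is a stack of k grayscale frames (default 96 × 128).
Each frame is tiled into a grid of blocks (default 6 × 8, so d = 48 blocks
of 16 × 16 pixels) and each block is summarised by its energy: the sum of
squared pixel intensities, with intensities on the [0, 1] scale so the
numbers are independent of 8-bit versus float input. Stacking the k
per-frame energy vectors gives the k × d energy matrix E. Rows of E encode
the spatial layout of a frame; columns trace one block through time.

The thin SVD E = U Σ Vᵀ separates this structure. The first left singular
vector u₁ carries the dominant, essentially static component of the scene.
Temporal change — blinks, pupil jumps, head-motion-induced shifts — lives in
the higher-rank vectors u₂, u₃, …, each a length-k time series. One of them
is selected as *the* eye-change signal:

* candidates are u₂ … u₁₀ (`max_rank = 10`; on a 600 × 48 decomposition,
  ranks beyond ~10 are dominated by pixel noise);
* each candidate is smoothed by a centred moving average (`window = 5`
  frames ≈ 167 ms at 30 FPS), mean-removed, and Fourier transformed;
* the winner has the largest single FFT-bin magnitude at frequencies inside
  `band = c(0.5, 15)` Hz — below 0.5 Hz lies DC and illumination drift,
  above sit blink transients (~0.3–1 s events) and saccade steps;
* ties break toward the lowest rank.

The selected vector is min–max scaled to [0, 1] and smoothed to give the
output signal; a constant vector maps to the information-free midpoint 0.5.

### Why the selection compares σ-weighted candidates

Left singular vectors are unit-norm, and min–max scaling would further
normalise each candidate's range to exactly [0, 1]. Selection on vectors
normalised that way is blind to how much temporal energy change a vector
actually describes: a rank-9 vector that is pure sensor noise spans its full
range just as the blink vector does, and white noise spread across many
bins can out-peak a transient-dominated blink vector. The comparison here
therefore runs on σⱼ·uⱼ — the actual rank-j contribution to E — smoothed
and mean-removed. "Highest frequency amplitude" then means amplitude of
real energy change, and noise-level candidates (tiny σⱼ) cannot win. The
alternative order (min–max scale each candidate first, then compare) is
available as `scale_before_select = TRUE`. Candidates whose singular value
is below 10⁻¹⁰·σ₁ contribute nothing to E and are treated as flat.

## Baselines

**EAR.** From six contour landmarks, EAR = (‖p₂−p₆‖ + ‖p₃−p₅‖) / (2‖p₁−p₄‖):
eye height over width, scale-invariant, ~0 when the eye is closed, and
blind to pupil position by construction. Missing values (failed detections)
are linearly interpolated, with edge gaps filled from the nearest
observation. The series is centred and scaled by the median and unscaled
MAD of the first 20 s of the session (participants are assumed focused at
the start); a zero calibration MAD falls back to the full-session MAD, then
to centring only. The robust z-score is the standard reading of "scaled
with median and MAD"; no 1.4826 consistency factor is applied since none is
specified.

**Gaze metrics.** From a horizontal iris track: a frame is a *saccade* when
|Δx| ≥ 1 pixel, a *fixation* when Δx = 0, and unlabeled for sub-threshold
non-zero motion (possible with sub-pixel tracking; the two defining rules
are not exhaustive there). Percentages divide by k − 1, the number of
frames with a predecessor, so a constant track has fixation share exactly 1.
Saccade velocity pools total absolute movement over all saccade frames;
a per-episode mean is available as an option.

## Features, selection, and evaluation

Signals are summarised by 15 statistical and 17 spectral descriptors.
Definitions the one-line descriptions leave open are pinned here: Shannon
entropy uses a 10-bin equal-width histogram normalised by log₂10 (constant
signal → 0); standard deviation, variance, kurtosis (excess, g₂) and
skewness (g₁) use the population denominator n; MAD-type features are
unscaled. All spectral features share one one-sided FFT of the raw,
unwindowed signal. Moment features (centroid, spread, skewness, kurtosis)
treat the normalised magnitude spectrum as a distribution over frequency;
maximum and median frequency are the 95% and 50% cumulative-magnitude
quantiles; power bandwidth is the width of the central 95%-power interval;
the fundamental frequency is the first non-DC local spectral maximum above
1% of the peak (guarding against numerical noise on line spectra). Wavelet
features come from a Ricker (Mexican-hat) continuous wavelet transform at
integer scales 1–9 (energy = RMS of coefficients per scale, variance =
population variance, entropy over per-scale absolute mass); scales 5 and 8
are the ones that matter downstream and are always present.

Feature elimination fits the 0/1 label on all features jointly by OLS (a
linear probability model, exactly as described for the reference pipeline)
and keeps features with coefficient p ≤ 0.05. No multiple-testing
correction is applied — a deliberate fidelity choice. A univariate mode
covers tables with more features than rows.

Evaluation uses stratified 5-fold cross-validation; training folds are
randomly undersampled to class balance, test folds never touched. Per-class
"accuracy" is that class's recall (the only reading under which separate
Focus and non-Focus accuracies are meaningful), F1 treats the class at hand
as positive, AUROC is threshold-free; all are reported as mean ± SD across
folds. XGBoost runs 1000 boosting rounds with its AUC metric computed on a
stratified 20% slice of the training fold held out as a validation set (no
early stopping — rounds are specified, stopping is not). The MLP is a
two-layer perceptron, 12 ReLU hidden nodes and one sigmoid output, trained
with binary cross-entropy and Adam (100 epochs, batch 16, seeded He
initialisation; epochs and batch are free parameters). Inputs to the MLP
are standardised by training-fold statistics. Note that XGBoost's default
`min_child_weight = 1` blocks all splits when the balanced training set is
very small (hessian 0.25 per row); `xgb_params` exposes the knob for such
tables.

## The synthetic study conditions

Real probed recordings are access-restricted, so every claim is exercised
on rendered sequences with known ground truth: 20 s at 30 FPS (600 frames)
of a 96 × 128 eye crop — a light sclera ellipse on darker skin, a dark iris
disc clipped by the eyelid opening, i.i.d. Gaussian pixel noise (σ = 4 grey
levels), with per-frame contour landmarks emitted consistently with the
drawn eyelid.

Behaviour regimes encode the attentional states: *Focus* has frequent small
horizontal saccades (60/min, 4 px jumps inside a ±8 px range, ≥ 8-frame
dwell); *non-Focus (fixation)* holds the pupil still; *non-Focus (head
motion)* adds slow sinusoidal translation (6 px) and rotation (5°) of the
whole eye. All regimes blink 12/min (4 blinks per window) with a symmetric
9-frame linear close–open ramp. Blink and saccade rates per attentional
state are not quantified in the source literature; these values are in the
physiological range for reading and screen viewing and are free parameters
of the generator, not claims about human behaviour.

Two rendering choices matter. First, the iris disc is moderately dark
(grey 170 against a 220 sclera) and small (radius 11 px), so a full-fissure
blink occlusion dominates the temporal energy variance while pupil motion
contributes a smaller, higher-rank component — the balance real eye crops
show, where the selected signal is blink-dominated with pupil ripples on
top. Making the pupil both large and high-contrast instead lets the
accumulated variance of pupil position overtake blinks, and the selected
vector degenerates to a pure gaze trace. Second, sequences are rendered
directly at crop resolution; the landmark-to-crop path is exercised
separately with synthetic landmarks on larger frames, since rendering a
whole face adds nothing testable.

What the generator does **not** emulate: eyelashes, eyebrows and lid
texture; vertical saccades (the gaze metrics are horizontal-only);
illumination drift; compression artefacts; landmark-detector failure modes
beyond i.i.d. jitter and wholesale missingness. Passing tests therefore
show that the pipeline recovers the events it models — they do not certify
performance on real webcam video, where the published effect sizes are far
smaller (AUROC near 0.57, not 0.9+ as on these clean synthetic conditions).

## Numerical conventions

* Pixel (r, c) has centre coordinate x = c, y = r; the eye centre sits at
  ((w+1)/2, (h+1)/2), which makes mirror symmetry exact.
* Frames not divisible by the block grid are cropped bottom/right to the
  largest tiling size.
* Each singular-vector pair is sign-fixed so the largest-magnitude element
  of uⱼ is positive, making decompositions reproducible across runs.
* The moving average truncates at the edges (shorter averages), never pads.
* Crop boxes expand by 25% of the box's own width/height per side (margins
  scale with the eye, not the frame), clamp to borders, and resize
  bilinearly; missing-landmark frames repeat the previous crop (linear
  interpolation is reserved for EAR values, where it is specified).
* Left eye by default throughout; both-eye averaging is a caller decision,
  not a hidden default.

## Problem sizes

The test suite and acceptance script run the full 600-frame, 96 × 128
pipeline for the phenomenology checks; the oracle-equivalence checks use
k, d ≤ 12 where a naive loop implementation is tractable; the end-to-end
discrimination study uses 120 sequences at the 5:1 label imbalance with
stratified 5-fold cross-validation; the null-calibration study uses 1000
replicates at n = 200. A worked end-to-end example:

```{r example, eval = FALSE}
p <- eye_scene_params(seed = 7)
sq <- generate_sequence(focus_regime(), p)
sig <- extract_svd_signal(sq$frames, fps = p$fps)
sig
#> <temporal_signal> source=svd, 600 frames @ 30 fps, selected rank 3
#>   range [0.003633, 0.6494]

fd <- simulate_feature_data(120, 5 / 6, seed = 1)
evaluate_cv(fd$svd_spectral$features, fd$svd_spectral$label,
            model = "xgboost", seed = 1)
#> <eval_report> xgboost, 5-fold stratified CV (seed 1)
#>   acc_focus     0.900 +/- 0.117
#>   f1_focus      0.944 +/- 0.070
#>   acc_notfocus  1.000 +/- 0.000
#>   f1_notfocus   0.830 +/- 0.161
#>   auroc         0.950 +/- 0.059
```

## Known limitations

* The method consumes eye crops; landmark detection quality is an input,
  not something the package can compensate for.
* Selection returns exactly one singular vector; genuinely independent
  simultaneous processes (e.g. strong head motion plus pupil activity) are
  only captured to the extent they mix into that vector.
* The EAR robust scaling assumes the first 20 s of a session are typical
  (focused); sessions that start with eyes closed break the calibration.
* Wavelet and entropy definitions follow the pinned conventions above;
  other libraries' variants of the same feature names will differ
  numerically.
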