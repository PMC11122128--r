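# eyesvd

Attentional-state ("Focus" vs "non-Focus") prediction from eye-image
sequences, built around an SVD-based one-dimensional temporal eye signal.

During webcam-based online learning, mind-wandering shows up in the eyes:
blink dynamics in the eyelid, fixations and saccades in the pupil. The
standard lightweight signal — the eye aspect ratio
EAR = (‖p₂−p₆‖ + ‖p₃−p₅‖) / (2‖p₁−p₄‖) from six contour landmarks — sees
only the eyelid; pupil information usually requires a separate, heavy gaze
tracker. This package extracts a single signal that carries both, from eye
landmarks alone:

1. each frame of a cropped eye sequence (96 × 128) is tiled into d blocks
   (default 6 × 8) and summarised by per-block energy (sum of squared
   intensities), giving a k × d energy matrix **E**;
2. the thin SVD **E** = U Σ Vᵀ separates a static low-rank component (u₁)
   from temporal change carried by the higher-rank left singular vectors;
3. among u₂…u₁₀, the vector whose smoothed, σ-weighted time course has the
   largest FFT magnitude inside 0.5–15 Hz is selected, min–max scaled to
   [0, 1], and smoothed — the temporal eye-change signal.

Statistical and spectral features of that signal (and of the EAR and
gaze-metric baselines) feed OLS p-value feature elimination and stratified
5-fold cross-validated XGBoost / MLP classifiers with training-fold
undersampling, reported as per-class accuracy/F1 and AUROC.

Because the probed video corpus the method targets is access-restricted,
the package ships a synthetic eye-sequence generator (blinks, saccades,
head motion, with ground-truth event logs) that makes every stage testable
end to end. See `vignettes/eyesvd-methods.Rmd` for the model, parameter
choices, and what the synthetic conditions do and do not show.

## Worked example

```r
library(eyesvd)

# a 20 s Focus-regime sequence: 4 blinks, active pupil saccades
p  <- eye_scene_params(seed = 7)
sq <- generate_sequence(focus_regime(), p)
sort(sq$log$blink_frames)
#> [1] 172 222 396 476

sig <- extract_svd_signal(sq$frames, fps = p$fps)
sig
#> <temporal_signal> source=svd, 600 frames @ 30 fps, selected rank 3
#>   range [0.003633, 0.6494]
```

The signal's four largest excursions sit at frames 171, 223, 397, 477 —
within one frame of the ground-truth blink apices — with smaller
fluctuations tracking the pupil. The same sequence's EAR signal shows the
blinks but is flat between them.

```r
# 120 sequences at the realistic 5:1 Focus:non-Focus imbalance, where the
# two states differ only in pupil activity
fd <- simulate_feature_data(120, 5 / 6, seed = 1)
evaluate_cv(fd$svd_spectral$features, fd$svd_spectral$label,
            model = "xgboost", seed = 1)
#> <eval_report> xgboost, 5-fold stratified CV (seed 1)
#>   acc_focus     0.900 +/- 0.117
#>   f1_focus      0.944 +/- 0.070
#>   acc_notfocus  1.000 +/- 0.000
#>   f1_notfocus   0.830 +/- 0.161
#>   auroc         0.950 +/- 0.059

evaluate_cv(fd$ear_stats$features, fd$ear_stats$label,
            model = "xgboost", seed = 1)$summary[5, ]
#>   metric mean sd
#> 5  auroc  0.5  0
```

The SVD-spectral features separate the states (AUROC 0.95) while the
EAR-statistical baseline is at chance — the mechanistic point of the
method: when the regimes differ only in pupil behaviour, the eyelid-only
signal carries no class information. On real webcam recordings the
published effect is much smaller; the synthetic conditions are clean by
design.

A thin CLI wraps the same functions
(`exec/eyesvd synth|evaluate|compare`).

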