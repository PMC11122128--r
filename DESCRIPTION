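Package: eyesvd
Title: SVD-Based Temporal Eye-Signal Extraction for Attentional-State Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a one-dimensional temporal eye-change signal from cropped
    eye-image sequences by singular value decomposition of a block-energy matrix,
    and predicts attentional state ("Focus" vs "non-Focus") from statistical and
    spectral features of that signal. Includes the eye-aspect-ratio (EAR) and
    iris-track gaze baselines it is compared against, a parameterised synthetic
    eye-sequence generator with ground-truth blink and saccade events, OLS
    p-value feature elimination, and stratified cross-validated evaluation with
    XGBoost and MLP classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    EBImage,
    pROC,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
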