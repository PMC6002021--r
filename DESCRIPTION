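Package: teneeg
Title: Tensor-Structured Spectral EEG Features and Higher-Order PLS
    Regression for Subjective Rating Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts band-wise spectral power, channel-pair power-difference
    and phase-difference features from multi-channel EEG epochs, organizes
    them either as a vectorized feature matrix or as a four-mode feature
    tensor (trials x channel x channel x frequency band), and predicts
    per-trial subjective ratings (overall impression, valence, arousal) with
    NIPALS partial least squares and higher-order partial least squares
    (HOPLS) tensor regression. Includes per-subject leave-one-out
    cross-validation with hyperparameter grid search, RMSE scoring,
    coefficient-magnitude feature attribution, a synthetic EEG study
    generator with known ground truth, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
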