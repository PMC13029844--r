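Package: gaitrank
Title: Person Identification from Ground Reaction Forces with Rank-Based
    Ensemble Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-set person identification from six-channel
    ground reaction force (GRF) gait cycles recorded on force plates.
    Provides a data model and file formats for stance-only, zero-padded
    GRF cycles; a synthetic gait-population simulator with a body-mass
    covariate and an asymmetric hand-carried load condition; four
    stance-aware time-series augmentation operators (band-limited noise
    injection, per-leg time shifting, left-stance window cropping with
    resampling, and same-class mixup) and their x9 training-set expansion;
    a harness of 1D deep time-series classifiers (CNN, CNN-LSTM-FC,
    1D ResNet, 1D ConvMixer, InceptionTime) trained with Adam and
    categorical cross-entropy, plus a fast deterministic nearest-centroid
    reference backend; and two rank-based ensemble fusion strategies
    (weighted rank-order voting and additive weighted Top-T voting with a
    tunable position/quality trade-off), with tie resolution, lambda
    sweeps, leave-one-out ablation and body-mass-gap error analysis under
    three train/test scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
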