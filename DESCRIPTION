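Package: emgvit
Title: Vision-Transformer Gesture Recognition for High-Density Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hand-gesture classification from high-density surface
    electromyography (HD-sEMG) grids with a compact vision transformer.
    Provides the full preprocessing chain (rectification, Butterworth
    envelope, mu-law companding, rest removal, channel decimation, sliding
    windows), a class-token transformer classifier trained with Adam and
    repetition-wise cross-validation, a motor-unit "micro" path
    (extension/whitening plus fixed-point ICA decomposition, spike-triggered
    averaging, peak-to-peak MUAP images), a frozen-backbone macro-micro
    fusion classifier, feature-based SVM/LDA and 3D CNN baselines, and a
    synthetic HD-sEMG generator that emits convolutive motor-unit mixtures
    with ground-truth spike trains so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    signal,
    e1071,
    MASS
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
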