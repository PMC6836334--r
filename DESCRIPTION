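Package: rusleaf
Title: Leaf Relative Water Content Estimation from Non-Contact Resonant
    Ultrasound Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating leaf relative water content (RWC) from
    non-contact resonant ultrasound spectroscopy (NC-RUS) transmission
    coefficient spectra. Includes a physics-based synthetic generator of
    drying experiments (lossy-plate transmission model with leaf-like
    acoustic trait priors), assembly of multi-band spectra onto a fixed
    601-point two-channel grid with a seven-method interpolation
    augmentation, extraction of the four resonance-derived parameters
    (peak magnitude, frequency, phase and normalized -6 dB bandwidth),
    leaf-grouped cross-validation with density-dependent RWC balancing,
    a compiled one-dimensional convolutional network regressor and a
    random-forest regressor on the derived parameters, and evaluation
    utilities (RMSE, Pearson correlation, regression lines, paired
    model comparison, repeated-measures interpolation checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    pracma,
    signal,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
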