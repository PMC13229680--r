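Package: leafspec
Title: Hyperspectral Leaf Chlorophyll Estimation with Spectral Augmentation
    and Weighted Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A small-sample chemometric pipeline for estimating leaf
    chlorophyll from visible/near-infrared reflectance spectra (400-1000 nm).
    Provides a SummarizedExperiment-backed container for labelled spectra,
    identifier matching and leakage-safe train/validation splitting,
    moving-average smoothing and split diagnostics, physically constrained
    spectral augmentation (additive Gaussian noise and smooth wavelength
    warping), three heterogeneous base regressors (NIPALS partial least
    squares, closed-form ridge, gradient-boosted trees) with cross-validated
    hyperparameter search, a convex-weighted ensemble calibrated against
    cross-validated mean squared error, red-edge and variable-importance
    diagnostics, an augmentation-grid experiment harness, and a synthetic
    leaf-spectrum generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
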