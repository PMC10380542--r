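Package: seedcascade
Title: Cascade Spectral Discrimination of Transgenic Rice Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discriminating genetically modified (GM) rice seeds
    from near-infrared hyperspectral and terahertz absorbance spectra. The
    package covers the full chain from spectral images to decisions:
    reflectance calibration, adaptive-threshold seed segmentation, per-seed
    mean-spectrum extraction, moving-average smoothing, airPLS baseline
    correction and band trimming; a two-phase cascade of one-dimensional
    multireceptive-field convolutional networks (variety first, then GM
    status within the predicted variety) trained with Adam and validation
    checkpointing; PLS-DA and one-vs-rest RBF-SVM chemometric benchmarks
    with stratified splits and cross-validation; characteristic-wavelength
    selection by activation maximization of the trained networks (guided
    backpropagation with an L1 sparsity penalty) and by the successive
    projections algorithm; and multiclass evaluation metrics. A synthetic
    spectra and hypercube simulator provides self-contained fixtures with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
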