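Package: octflow
Title: Neural-Network Velocimetry and Flow-Rate Quantification for OCT
    Speckle Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies blood flow from optical coherence tomography (OCT)
    intensity time-series measurements acquired with a stepped M-scan
    protocol. Provides a forward speckle simulator of point scatterers
    translating through a Gaussian beam, an SNR-stratified bank of 1D
    convolutional velocity classifiers trained on simulated signal
    libraries, a Doppler (phase-difference) reference analysis with
    bulk-motion correction and two-dimensional phase unwrapping, and a
    flow-rate quantification layer with aperture masking, paraboloid
    extrapolation and calibration. A synthetic phantom generator produces
    complex-valued stepped M-scan B-scans with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rlang,
    stats,
    tools,
    utils,
    generics,
    tibble,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
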