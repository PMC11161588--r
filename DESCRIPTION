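Package: attnconn
Title: Background Connectivity and Dynamic Causal Modeling of the
    Attentional Spotlight in Retinotopic Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyzes retinotopic BOLD time series to
    localize the effect of focal versus diffused spatial attention on
    cortico-cortical coupling. Provides a synthetic block-design fMRI
    generator with a latent background-coupling field, nuisance and
    finite-impulse-response (FIR) residualization, eccentricity-binned
    background-connectivity profiles with repeated-measures statistics,
    a bilinear dynamic causal model (DCM) with balloon hemodynamics
    inverted by variational Laplace, random-effects Bayesian model
    selection by exceedance probability, and a moment-based estimator of
    stimulus-field center and size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
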