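Package: tvgc
Title: Time-Varying Conditional Granger Causality for Trial-Based
    Hemodynamic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits time-varying multivariate autoregressive (tvMAR) models to
    trial-epoched multichannel hemodynamic signals with a self-tuning
    Kalman filter, computes time-resolved conditional Granger causality for
    every ordered channel pair via spectral factorization of the fitted
    model, summarizes pre/post connectivity changes at the region level as
    directed increases and decreases, and assesses their significance with
    trial-label permutation tests under false discovery rate control.
    Includes preprocessing for hemodynamic-band signals (zero-phase
    Butterworth filtering, bidirectional-pathway averaging, epoching with
    baseline correction) and a synthetic-data generator with known
    ground-truth directed couplings plus closed-form Granger-causality
    oracles for stationary networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
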