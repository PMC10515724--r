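Package: hybridfb
Title: Deep Hybrid Modeling of Fed-Batch Cell Culture Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid semi-parametric modeling of fed-batch bioreactor processes:
    macroscopic material-balance ordinary differential equations coupled in
    series with a deep feedforward neural network that supplies the specific
    reaction rates. Provides fixed-step Runge-Kutta integration of the hybrid
    system, exact gradient computation by indirect and semidirect sensitivity
    equations, classical Levenberg-Marquardt training with noise-augmented
    cross-validation, ADAM training with stochastic regularization (minibatch
    subsampling and hidden-node dropout), weighted mean squared error and
    small-sample corrected Akaike information criterion model selection with
    batch-wise resampling, and a synthetic CHO-like fed-batch data generator
    built on a central composite design over feed rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
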