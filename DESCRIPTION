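Package: oscibin
Title: Mean-Field and Linear-Response Analysis of Periodically Driven
    Binary Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how an oscillatory drive shapes the
    cyclostationary mean activities and zero-lag pairwise covariances of
    recurrent random networks of binary (0/1) neurons. Implements the
    Gaussian mean-field moment equations for population means and
    covariances, self-consistent stationary solutions with threshold
    calibration to target activities, closed-form linear-response
    (first-harmonic) solutions for means and covariances including the
    mechanistic decomposition of covariance modulation into direct-drive,
    recurrent-drive and modulated-autocovariance contributions, a stochastic
    event-driven Glauber-dynamics simulator with phase-resolved
    (cyclostationary) ensemble statistics, and frequency-sweep orchestration
    across the analytic, numerical-ODE and simulation layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
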