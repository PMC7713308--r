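Package: arstrack
Title: Switching State-Space Movement Models and Behaviour-Seascape
    Analysis for Argos Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring area-restricted-search (ARS) behaviour from
    Argos satellite telemetry of marine megafauna. Provides Argos track
    reading, gap-based segmentation and quality-class handling; a Bayesian
    two-state switching first-difference correlated random walk state-space
    model fitted by Markov chain Monte Carlo, yielding regular-interval
    location and behavioural-state posteriors; weighted-day occupancy
    gridding and per-animal track metrics; seascape covariate extraction
    with temporal lags, spatial-window statistics and collinearity
    screening; binomial additive mixed models of behaviour on seascape
    smooths with multiple-imputation propagation of location and state
    uncertainty; and a synthetic-data generator that emulates Argos
    sampling so the whole pipeline is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    mgcv,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    coda,
    rjags,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
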