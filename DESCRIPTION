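Package: rrlogistic
Title: Range-Resident Logistic Model for Movement-Coupled Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based birth-death simulation of a single-species
    logistic population whose organisms are range residents: they move by an
    Ornstein-Uhlenbeck home-range process and compete through a Gaussian
    spatial kernel that raises death rates with local crowding. Demography is
    simulated exactly with Gillespie's algorithm on a periodic square domain;
    Brownian (uniform space use) and sessile movement arise as limiting
    cases. Includes crowding-index estimators from organism positions or from
    home-range centres and sizes, a torus pair-correlation estimator, the
    first-order mean-density theory that predicts carrying capacity from the
    crowding index, and replicate sweep orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
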