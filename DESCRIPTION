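Package: hydroniche
Title: Water-Source Partitioning and Stability of Revegetated Dryland Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how co-occurring plant functional groups (shrubs,
    semi-shrubs, herbs) partition soil water across depth in a dryland
    revegetation chronosequence, using dual stable isotopes of water.
    Provides a synthetic-data generator emulating the isotope structure of
    such studies, meteoric water line regression and d-excess utilities, a
    from-scratch Bayesian dual-isotope mixing model (Dirichlet prior,
    residual error, MCMC on log-ratio coordinates) for soil-layer source
    apportionment, the herb-to-shrub water-use ratio statistic with its
    stability thresholds, and a two-compartment shrub-herb biomass model
    with analytic Jacobian, eigenvalue stability classification,
    bifurcation scanning, and regime calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
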