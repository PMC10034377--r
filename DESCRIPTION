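Package: aquacal
Title: Uncertainty-Aware Bayesian Calibration of a Water-Driven Crop Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A daily-time-step water-driven crop growth simulator in the
    AquaCrop family (soil water balance, canopy cover dynamics,
    transpiration/evaporation partitioning, biomass via normalized water
    productivity, yield via harvest index), together with the tools needed
    to calibrate it on multi-field observation campaigns and to quantify
    the resulting prediction uncertainty: Morris elementary-effects
    screening with output rescaling and season/variable averaging,
    delayed-rejection adaptive Metropolis (DRAM) sampling under uniform
    priors with per-variable error-variance estimation, data
    stratification by cultivar and growing period, and Monte-Carlo
    propagation of posterior draws to biomass/yield summarized by mean and
    mean absolute deviation. Includes a synthetic-campaign generator
    (weather, soils, noisy field observations with known true parameters)
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
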