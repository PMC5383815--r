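Package: sealsearch
Title: Detecting and Modelling Benthic Foraging Search Events from Seal-Borne Motion Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying foraging behaviour of benthic-foraging
    seals from animal-borne tri-axial motion sensors. Derives attitude
    (pitch, roll, yaw), overall dynamic body acceleration (ODBA) and gyroscope
    RMS from raw accelerometer, magnetometer and gyroscope streams; segments
    dives from the pressure-derived depth channel; detects head-down search
    events with a joint pitch/depth threshold rule; joins per-dive
    environmental covariates from gridded rasters; and fits a Bayesian
    hierarchical logistic regression of search occurrence with per-seal random
    intercepts via a Polya-Gamma Gibbs sampler. Includes a synthetic-data
    generator with known ground truth for validating the detector and the
    model, and broom-style tidiers plus ggplot2 visualisations for all result
    types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
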