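Package: transloc
Title: Free-Energy Analysis of Peptide Translocation Across Asymmetric
    Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing umbrella-sampling free-energy
    calculations of peptide translocation across symmetric and
    asymmetric lipid bilayers.  Provides a self-consistent weighted
    histogram analysis method (WHAM) solver with overlap diagnostics
    and moving-block bootstrap errors, alignment and joining of
    translocation subprocess profiles into full directional paths,
    directional translocation barriers and permeability models
    (serial-resistance versus a corrected barrier estimator),
    leaflet tensions from lateral pressure profiles, and
    classification of mimicking versus intermediate regions of
    asymmetric-membrane profiles.  A synthetic-data module generates
    parametric translocation landscapes, umbrella window schemes,
    biased Boltzmann sampling, and stress profiles with closed-form
    leaflet tensions so that every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
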