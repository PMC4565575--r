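Package: ectoplan
Title: Treatment Planning for Electrochemotherapy with Long Needle Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning electroporation-based treatments delivered
    through arrays of single long needle electrodes. Generates synthetic
    voxel anatomy (tumors, vessels, bone, safety margins), models star
    electrode arrays and pulse-pair schedules, solves the nonlinear
    electrostatic field problem with electroporation-dependent tissue
    conductivity on the voxel grid, predicts per-pair currents, aggregates
    cumulative field coverage and coverage-volume histograms, assesses plan
    robustness to placement and conductivity uncertainty, optimizes electrode
    position and voltages, and exports navigation-ready marked trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
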