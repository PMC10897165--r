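Package: zebratrax
Title: Zebrafish Behavioral Phenotyping from Centroid Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of zebrafish open-field and light/dark photomotor assays
    from 2-D centroid tracking data. Provides arena and light-schedule
    definitions, tracking-file input/output with jitter suppression,
    per-minute activity binning and photomotor light/dark response ratios,
    thigmotaxis and social-preference zone occupancy, occupancy heatmaps,
    rule-based classifiers for three repetitive behaviors (back-and-forth
    excursions, stereotypic confined swimming, and large circling detected by
    signed-angle winding), shoaling interindividual distance, group
    comparisons with unpaired t tests, and an agent-based correlated
    random-walk simulator that emits ground-truth bout labels for validating
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
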