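Package: tailbalance
Title: Tail-Mediated Balance Analysis for Rodent Ridge-Crossing Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline for two-view markerless-tracking
    keypoint trajectories of mice crossing a narrow, tiltable ridge.
    Reads DeepLabCut-style keypoint tables, conditions them on tracking
    likelihood, computes roll- and yaw-plane angle traces (tail, hip,
    back, front), segments step cycles from hind-paw trajectories,
    derives balance-performance metrics from the top-view body centroid,
    estimates tail, body and perturbation angular momentum with a
    rod-and-cylinder biomechanical model, and builds step-cycle-aligned
    tail-body momentum cross-correlograms with hotspot detection.
    Includes a synthetic-trajectory generator with known ground truth
    for validation, and classical group statistics (one-way ANOVA,
    Bonferroni post hoc, pooled t-tests, mean +/- s.e.m.).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
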