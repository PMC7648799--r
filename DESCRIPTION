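Package: moseg
Title: Multi-Organ Segmentation and Annotation-Uncertainty Analysis for
    Whole-Body Mouse Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for delineating multiple organs in
    volumetric whole-body mouse scans with a configurable encoder-decoder
    convolutional network trained slice-wise on coronal sections with a
    soft-Dice loss. Includes subject-level cross-validated training,
    ensemble median voting, prediction of inter-annotator disagreement as
    a heatmap, segmentation quality metrics (epsilon-smoothed Dice,
    percentile Hausdorff surface distance, center-of-mass displacement,
    union-reference Dice), organ volumetry with intersubject,
    interannotator and intraannotator variability decompositions, and
    metastasis-to-organ allocation. A synthetic phantom generator emulates
    cohorts of mice scanned at several timepoints with posture jitter,
    organs of differing contrast and two annotators, so the whole pipeline
    is testable without external data. Volumes are read and written in the
    NIfTI format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
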