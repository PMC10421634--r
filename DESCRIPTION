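Package: ethokit
Title: Unsupervised Behavioral Decomposition from 3D Pose Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying animal behavior from markerless 3D pose
    tracking. Implements a full analysis pipeline for multi-session landmark
    recordings: quality control, gap interpolation and per-frame similarity
    normalization of poses; mutual-nearest-neighbor batch alignment across
    sessions; joint-angle and speed feature engineering with PCA reduction; a
    2-D nonlinear embedding with kernel-density watershed segmentation into
    postures; lag-T posture transition graphs; Paris hierarchical graph
    clustering with modularity-maximizing dendrogram cuts, Dasgupta scores and
    adjusted mutual information; exponential timescale (half-life) fits of
    modularity and stability curves; and permutation-based significance tests
    with two-way ANOVA group comparisons. Includes a synthetic pose-data
    generator with planted posture, module and hierarchy structure so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    Matrix,
    MASS,
    EBImage,
    minpack.lm,
    car,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    optparse,
    patchwork
Config/testthat/edition: 3
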