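Package: fagnn
Title: Quadrant-Attention Graph Neural Networks for Brain Age Prediction
    from Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Connectome", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts brain age from mouse structural connectomes together
    with risk-factor traits (APOE genotype, NOS2 variant, sex, diet) and
    Morris Water Maze behavioral matrices.  A quadrant attention module
    scores every region-pair connection with per-hemisphere-block multihead
    attention; the score-weighted graph is processed by a degree-normalized
    graph convolutional network with top-K pooling, fused with 1D/2D
    convolutional embeddings of traits and behavior, and regressed onto
    chronological age with a per-subnetwork-learning-rate Adam optimizer.
    Includes fivefold cross-validation with repeated runs and ablations,
    group-transfer delta-MAE evaluation, brain-age-delta group comparisons,
    edge-importance ranking, an along-tract Kruskal-Wallis / Dunn / Holm
    statistical battery, and a synthetic aging-cohort simulator with
    planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
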