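Package: tgindex
Title: Temporal Grading Index Analysis of Dynamic Brain Network Topology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for sliding-window dynamic functional connectivity
    analysis of parcellated resting-state fMRI time series. Builds windowed
    Pearson-correlation networks with negative and self connections removed,
    computes weighted nodal graph metrics (degree, clustering coefficient,
    participation coefficient) per window, derives the temporal grading
    index (TGI) -- the per-region regression slope of a patient's deviation
    from the healthy-control norm against that norm across windows -- and
    predicts pain intensity from TGI features with penalized regression
    (SVR, lasso, elastic net) under repeated k-fold cross-validation with a
    training-set bias adjustment. Includes a synthetic-cohort generator
    emulating a two-group chronic back pain study design, motion-based
    quality control, and covariate-adjusted group statistics with FDR
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
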