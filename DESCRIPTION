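Package: tempaxis
Title: Temporal and Differentiation Axis Decomposition for Single-Cell
    Progenitor Transcriptomes
Version: 0.1.0
Authors@R:
    person("tempaxis", "maintainers", email = "tempaxis@example.org",
           role = c("aut", "cre"))
Description: Tools to separate a temporal axis (developmental time) from a
    differentiation axis (apical versus intermediate progenitor identity) in
    single-cell expression profiles of cortical progenitor cells.  Provides a
    synthetic-data generator with known latent coordinates and spike-in
    calibration transcripts, spike-in based detection filtering and sample
    quality control, marker-gate cell classification, hierarchical clustering
    with multiscale-bootstrap approximately-unbiased (AU) cluster support,
    stage-wise differential-expression selection (ANOVA, q-values, log
    fold-change thresholds), constrained rotation of the leading principal
    components into temporal and differentiation axes, and projection of
    perturbed (cell-cycle-arrested) cells onto a wild-type reference temporal
    component with nonparametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
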