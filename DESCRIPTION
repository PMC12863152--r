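Package: mseeg
Title: Resting-State EEG Microstate Segmentation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into microstates:
    global field power (GFP) computation and peak extraction, polarity-invariant
    atomize-agglomerate hierarchical clustering (AAHC) of GFP-peak topographies,
    canonical A-D template sorting, backfitting to a continuous label stream,
    and estimation of microstate temporal parameters (duration, occurrence,
    coverage) and first-order transition probabilities.  Includes a synthetic
    EEG generator with known microstate ground truth for validation by
    parameter recovery, and a group-statistics layer (socioeconomic-status
    composite scoring, extreme-group splits, Pearson correlations,
    repeated-measures ANCOVA with covariates, Bonferroni post hocs, and
    transition t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
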