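Package: microscreen
Title: Morphometric Analysis of Microscopy-Based siRNA Screens in Microglia
Version: 0.1.0
Authors@R:
    person("Screen", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify microglial cell-shape phenotypes in
    image-based RNA-interference screens. Implements per-cell circularity
    morphometry (median filtering, automatic thresholding, sub-pixel
    contour perimeter estimation, border-cell exclusion), screen-level
    statistics (per-experiment normalization against a scrambled-siRNA
    control, moderated one-sample t-tests with empirical-Bayes variance
    shrinkage, Benjamini-Hochberg false discovery rates, hit
    classification and multi-siRNA validation), wound-healing scratch
    assay quantification, and delta-delta-Ct relative expression
    analysis. A synthetic-data module generates cell-field images with
    analytic ground truth, full simulated screens with planted effects,
    scratch image pairs, and Ct tables, so the entire pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
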