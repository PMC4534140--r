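Package: epiqpcr
Title: ChIP-qPCR Enrichment Analysis with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies histone-modification enrichment (e.g. H3K4me3,
    H3K27ac) at candidate loci from ChIP-qPCR cycle-threshold tables using
    the delta-Ct percent-input method, with primer-efficiency calibration
    from dilution series, IgG negative-control quality filters, per-sample
    normalization, and robust outlier flagging.  Two-group inference uses
    Monte-Carlo permutation tests for means and variances with
    Benjamini-Hochberg adjustment across loci, complemented by classical t-
    and F-tests, one-way MANOVA, PCA with permutation tests of axis and
    diagonal splits, and Ward hierarchical clustering with deepest-split
    tests.  A synthetic-data module generates Ct tables with known ground
    truth so the whole pipeline can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
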