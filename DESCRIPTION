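Package: pdmg
Title: Cross-Modality Consensus Signatures of Disease Microglia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for defining a cross-modality consensus
    transcriptional signature of Parkinson's disease microglia from bulk and
    single-nucleus differential expression, and for classifying spatial
    transcriptomics microglia into consensus and non-consensus classes.
    Includes negative-binomial and Wilcoxon differential expression with
    TMM normalization, single-sample gene-set enrichment scoring,
    hypergeometric over-representation analysis, variance-weighted
    non-negative least squares deconvolution of bulk profiles against a
    multi-donor single-cell reference, transcript-to-cell assignment from
    segmentation label masks, and a synthetic multi-modal data generator
    with planted ground truth so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    edgeR,
    jsonlite,
    methods,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
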