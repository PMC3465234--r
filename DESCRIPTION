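Package: mlconsensus
Title: Mixed-Length Consensus Models for Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds consensus models of transcription factor binding sites
    directly from variable-length site collections, without discarding any
    reported site. Provides a naive sorting-based greedy multiple aligner, an
    ambiguity-code consensus over two-base codes, and four scanning scores
    (match count, information-content weighting, pairwise co-occurrence over
    a bounded scope, and their combination), together with a leave-one-out
    cross-validation harness: slot-based ROC curves over a capped
    false-positive-rate range, sum-of-TPR areas, Wilcoxon matched-pair
    signed-ranks comparisons between configurations, and detection of the
    significance plateau across pairwise-score scopes. A seeded synthetic
    dataset generator with a planted core motif makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
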