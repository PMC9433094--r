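Package: crossomix
Title: Crosswise Integration of Transcriptome and Chromatin Accessibility
    Networks for Perturbation-Informed Sensitivity Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-fold-change (GFC) based co-expression networks from
    RNA-seq and promoter-ATAC-seq count matrices, merges cell-line networks
    horizontally and integrates the two omic layers vertically by correlating
    module regulation patterns. Selected cross-layer modules are distilled,
    through a baseline differential-expression filter, into up/down gene
    signatures of drug sensitivity; per-sample enrichment scores (GSVA-style
    and ssGSEA-style) yield a sensitivity score, and an L1-penalised
    regression learns to reproduce that score from basal transcriptomes
    alone. A negative-binomial simulator with planted co-regulated modules
    and latent-sensitivity cohorts makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    Matrix,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
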