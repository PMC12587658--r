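Package: ervcre
Title: Identification of ERV-Derived Cis-Regulatory Elements and Their
    Dysregulation in Preeclampsia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for identifying endogenous
    retrovirus (ERV) derived cis-regulatory elements active in trophoblast
    and their dysregulation in preeclampsia. Provides a seeded synthetic-data
    generator with planted ground truth, a 1D convolutional neural network
    enhancer classifier over one-hot encoded DNA with a GC-content side
    feature, ChIP peak/repeat intersection with reciprocal-overlap semantics
    and deepTools-style signal matrices, 15-kb upstream ERV-gene expression
    pairing by Spearman correlation with Benjamini-Hochberg control, AP-1
    position-weight-matrix scanning of LTR consensus sequences, and the
    preeclampsia dysregulation stage (DEG filtering, batch centering,
    relative abundance, hypergeometric enrichment, shared-DEG correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
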