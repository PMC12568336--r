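Package: loopscape
Title: Micro-C Contact Map Analysis and Enhancer-Promoter Loop Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for Micro-C ligation-pair data from pair-level quality
    control to annotated enhancer-promoter loops. Implements chimeric read-pair
    filtering, deduplication and interaction classification with summary
    accounting, library-complexity modelling, sparse binned contact matrices
    with ICE balancing, contact-probability decay curves, A/B compartment
    calling by eigendecomposition with saddle-plot compartmentalization
    strength, insulation-score TAD boundary detection, distance-stratified
    binomial interaction significance with observed/expected enrichment and
    FDR, local-neighborhood chromatin loop calling, epigenomic loop-anchor
    annotation, structural-variant overlap, and promoter-anchored interaction
    extraction. Ships a synthetic pair generator with planted compartments,
    domains and loops so that every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
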