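Package: isoforge
Title: Isoform-Resolved Transcriptome Construction and Characterization for
    Early Embryonic Development
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build and characterize an isoform-resolved transcriptome
    from long-read transcript models and short-read junction evidence, modelled
    on the analysis of human preimplantation embryos. Implements structural
    classification of candidate isoforms against a reference annotation (known,
    ISM, NIC, NNC, antisense, intergenic), transcript-model collapsing,
    intra-priming and junction-support filters, sequence-feature
    characterization (ORFs, Fickett/hexamer coding potential, poly(A) motifs,
    repeat projection and transposable-element roles, conservation hit calls),
    alternative-splicing event extraction with percent-spliced-in dynamics and
    fuzzy c-means temporal clustering, and a signed co-expression network layer
    with module eigengenes, novelty enrichment and correlation-filtered
    regulatory networks. A fully labelled synthetic-data generator provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    igraph,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
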