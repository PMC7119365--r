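Package: silknet
Title: Co-Expression Networks and Selection Scans for Silk-Gland
    Transcriptome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for comparative transcriptomics of the
    silkworm silk gland between domesticated and wild populations: TMM
    normalization and FPKM quantification, stage-matched differential
    expression by a negative-binomial exact test with Benjamini-Hochberg
    correction, weighted gene co-expression networks with soft
    thresholding and topological overlap, module detection and
    cross-condition consensus modules, differential co-expression around
    silk-protein seed genes, sliding-window nucleotide diversity and Fst
    scans for artificial-selection signatures, and hypergeometric
    enrichment. A seeded synthetic-data generator plants modules,
    differential edges, differentially expressed genes and selective
    sweeps so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
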