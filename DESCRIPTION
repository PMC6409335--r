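Package: adipolinc
Title: LincRNA Identification and Functional Prediction for Adipose RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering long intergenic non-coding RNAs
    (lincRNAs) from an assembled transcriptome and predicting their function
    in a two-group adipose RNA-seq design. Classifies assembled transcripts
    against a reference annotation, applies a multi-stage lincRNA filter
    cascade (structure, ORF-based coding potential, protein homology
    evidence, expression), computes FPKM and class characterizations, tests
    two-group differential expression with a negative-binomial Wald engine,
    predicts cis target genes from genomic proximity (<100 kb) and Pearson
    correlation of expression, and colocalizes differentially expressed
    lincRNAs with QTL intervals. Ships a seeded synthetic-study generator
    with planted ground truth so every stage is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
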