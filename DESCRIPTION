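Package: gcn4scope
Title: Bin-Based ChIP-Seq Peak Calling and Regulon Analysis for Gcn4-Class
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for dissecting the regulon of a
    bZIP transcription factor such as yeast Gcn4 from matched ChIP-seq and
    RNA-seq experiments.  Implements a transparent bin-based peak caller with
    mode/MAD background normalization and two-replicate consensus, peak-to-gene
    target assignment and genomic-feature classification, IUPAC consensus motif
    scanning (TGANTCA), anchor-centered coverage matrices, integration of
    differential-expression tables into a direct/indirect x activated/repressed
    regulon classification, arginine/lysine proteome-composition binning with
    gene-set enrichment, and a fully seeded synthetic-data generator that
    plants ground-truth peaks, expression effects and proteome composition so
    every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
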