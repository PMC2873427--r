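Package: allelesplice
Title: Allelic Gene Structure Variation and Alternative Splicing from EST Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcript structure variation (TSV) events from spliced
    EST-to-genome alignments, classifies them into six structural categories
    (intron retention, alternative acceptor, alternative donor, alternative
    donor-and-acceptor, exon skipping, others), calls mismatch SNPs between
    ESTs and the reference genome with a multi-EST (mSNP) false-positive
    filter, and uses linked SNP patterns shared between isoform-supporting
    EST groups to decide whether each event arises from allelic gene
    structure variation or from post-transcriptional alternative splicing.
    Includes coding-impact annotation against gene models (CDS/UTR location,
    reading-frame preservation) and a fully specified synthetic-data
    generator with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
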