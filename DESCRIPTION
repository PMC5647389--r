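Package: peaktargets
Title: Nominate Direct Transcription-Factor Targets from ChIP-seq Peaks and RNA-seq Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strand-aware classification of ChIP-seq peak summits relative to
    transcript models (proximal/distal promoter, exonic, intronic, intergenic),
    genomic-distribution summaries, intersection of peak-associated genes with
    differentially expressed genes, hypergeometric term enrichment with
    Benjamini-Hochberg FDR control, and fixed-word motif cluster scanning.
    Readers are provided for Ensembl-dialect GTF gene models, ENCODE narrowPeak,
    MACS14 peak tables, BED blacklists and Cuffdiff differential-expression
    tables, together with seeded synthetic-data generators that emit every
    input format with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
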