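Package: gtscreen
Title: Analysis of Haploid Gene-Trap Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for FACS-based forward genetic screens in near-haploid
    human cells mutagenized with a gene-trap retrovirus. Derives unique
    insertion sites from 36-bp LTR-junction read alignments using strict
    uniqueness and near-duplicate collapse rules, classifies intragenic
    insertions by orientation and exon/intron placement, tests per-gene
    enrichment of inactivating insertions in sorted versus control
    populations (one-sided Fisher exact test with Benjamini-Hochberg FDR),
    scores intronic insertion orientation bias (IGTIOB), and compares hits
    across screens by complete-linkage clustering of IGTIOB profiles. A
    synthetic-screen generator with TSS-biased integration and selectable
    allele classes makes the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
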