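Package: mirptr
Title: Master MicroRNA Regulator Inference from Paired Transcription and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Morgan", "Reyes", email = "mreyes.bioinf@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis pipeline for nominating master microRNA
    regulators in two-condition (tumor versus normal) designs. Implements
    negative-binomial differential miRNA abundance testing with a batch
    covariate and variance-based selection filters, quantification of
    nascent transcription over miRNA loci anchored at the nearest upstream
    transcriptional regulatory element, classification of genes under gain
    or loss of posttranscriptional regulation from paired transcription
    (ChRO-seq/PRO-seq) and steady-state expression (RNA-seq) differential
    tables, and a Monte-Carlo 3'UTR seed-site enrichment test. A synthetic
    data module generates every pipeline input with known ground truth so
    that each stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    Matrix,
    optparse,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
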