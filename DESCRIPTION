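Package: psikit
Title: Bayesian Splicing Quantification, Event Classification and RBP
    Motif Enrichment for Two-Condition RNA-Seq
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying condition-dependent alternative splicing
    from junction read counts: a two-isoform Bayesian model for percent
    spliced in (PSI) with Bayes-factor tests of differential splicing,
    threshold-based classification of skipped-exon and retained-intron
    events into regulatory groups, minor-spliceosome (U12) intron
    flagging, pentamer RNA-binding-protein motif enrichment against
    GC-binned first-order Markov backgrounds, reading-frame consequence
    annotation of retained introns (premature termination codons and
    nonsense-mediated-decay candidacy), and delta-delta-Ct qPCR
    quantification.  A synthetic-data generator with known ground truth
    supports end-to-end testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
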