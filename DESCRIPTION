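Package: metaribo
Title: Community Ribosome Profiling: Simulation, smORF Discovery and
    Translational Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for ribosome profiling of mixed microbial
    communities (MetaRibo-Seq-style experiments). Provides a ground-truth
    synthetic-community simulator (genomes with planted ORFs and small
    ORFs, lognormal transcription and translational-efficiency models,
    footprint reads with start/stop-codon peaks and triplet periodicity),
    a six-frame ORF scanner, an exact-match read mapper with a
    perfect-and-unique alignment filter, metagene and reading-frame
    diagnostics, strand-enforced feature counting with RPKM-based
    translation-evidence calls, greedy identity clustering of protein
    families with homolog assignment and enrichment statistics,
    negative-binomial differential tests of transcription and translation
    (including the condition-by-assay interaction that detects
    translational regulation), and gene-based taxonomy propagation with
    genomic-neighborhood and localization summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
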