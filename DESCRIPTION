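Package: phanner
Title: Deep-Sequencing Analysis of Phage-Display HCDR3 Selection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing multi-round phage-display
    panning experiments read out by paired-end deep sequencing of degenerate
    HCDR3 (heavy-chain complementarity-determining region 3) libraries. Provides
    barcode demultiplexing, anchored 27-nt HCDR3 extraction with a paired-read
    (R2) fallback, amber-suppressed translation (TAG read as glutamine), unique
    nucleotide and peptide counting per pool, round-over-round fold-change
    enrichment with stratification, and positional diversity statistics
    (Shannon entropy, Weblogo-style information content, and Kullback-Leibler
    divergence between selection rounds). A synthetic-data generator emulates a
    degenerate (NNS)6 KBG HTK GMT codon library under multinomial selection and
    emits barcoded paired-end FASTQ with known ground truth, so the whole
    analysis is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
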