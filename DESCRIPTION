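Package: famforge
Title: Gene-Family Survey Pipeline with Simulated Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end survey pipeline for plant gene families such as the
    rice proton-dependent oligopeptide transporter (PTR/POT) family: profile
    and keyword screening of candidate proteins, tandem and segmental
    duplication detection, neighbor-joining phylogenetics with bootstrap
    support and subfamily cutting, conserved-motif extraction with
    relative-entropy logos, microarray-style expression profiling with
    preferential/tissue-specific/differential calling, Nei-Gojobori Ka/Ks
    selection analysis on codon alignments, and classification of paralog
    expression fates (duplication, nonfunctionalization, subfunctionalization,
    neofunctionalization). A synthetic-data module generates genomes, codon
    sequences, planted motifs and replicate expression matrices with known
    ground truth so every stage is testable without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
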