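Package: crossreg
Title: Promoter-Level Cross-Regulation Analysis of NF-kB and IRF
    Transcription-Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for promoter-level analysis of
    cross-regulation between the NF-kB and IRF transcription-factor
    families: position-weight-matrix and IUPAC-consensus scanning of
    promoter sequences, cross-species conservation filtering of predicted
    binding sites (phylogenetic footprinting), per-gene binding-site count
    tables with overlap detection, AU-rich element (ARE) classification of
    3'UTRs, Monte-Carlo random-sequence background specificity testing,
    and cross-referencing of predictions with ChIP-seq peak files.
    Includes a fully seeded synthetic-data generator with machine-readable
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
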