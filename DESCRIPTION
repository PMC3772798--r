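Package: peptox
Title: Peptide Toxicity Prediction from Sequence Composition, Quantitative
    Matrices and Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A trainable toolkit for classifying short peptides (<= 35
    residues) as toxic or non-toxic from sequence alone. Provides amino acid
    and dipeptide composition encoders, terminal-window one-hot profiles,
    position-specific quantitative matrices with cumulative scoring,
    a support-vector-machine harness with motif-augmented hybrid rescoring,
    desk-scale motif discovery and scanning with exact null p-values,
    stratified cross-validated evaluation (sensitivity, specificity,
    accuracy, MCC, AUC), peptide design utilities (single-mutant enumeration
    and ranking, sliding-window protein scanning), a seeded synthetic
    peptide generator for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
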