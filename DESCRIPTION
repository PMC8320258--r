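Package: tcrscreen
Title: Identify Antigen-Specific T-Cell Receptors from Single-Cell
    Activation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying neoantigen-specific T-cell receptors
    (TCRs) from stimulated tumor-infiltrating T cells profiled by
    high-throughput single-cell V(D)J sequencing with targeted enrichment
    of activation markers (IFN-gamma, IL-2) and lineage markers (CD4,
    CD8A, CD8B). Reads 10x-style contig annotation tables and per-barcode
    marker UMI matrices, calls clonotypes by CDR3-beta nucleotide
    identity, applies UMI positivity thresholds, removes autoreactive
    clonotypes using a negative-control stimulation, classifies candidate
    receptors as shared (two or more activated cells) versus unique
    (one cell), and computes merged clonotype frequencies after singleton
    removal. Includes a seeded droplet-level simulator of immune
    repertoires (doublets, dual TCR-alpha cells, sequencing-error
    singleton clonotypes, ambient marker counts) with six reference
    specimen fixtures, a validation harness that scores candidate calls
    against planted truth, and a hard filter for somatic variant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    Matrix,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vctrs,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
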