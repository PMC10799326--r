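Package: famhist
Title: Gene-Family Duplication and Loss Histories for Tardigrade
    Extremotolerance Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for reconstructing the evolutionary history of
    gene families linked to desiccation and radiation tolerance in tardigrades
    (CAHS, MAHS, SAHS, EtAHS alpha/beta, MRE11). Provides homology-screen
    decision rules over BLAST tabular hit files, RCFV-based compositional
    outlier screening of protein alignments, support-aware collapse and rooting
    of gene trees, genus-level duplication and loss inference by LCA
    reconciliation with the genus-exclusive independent-duplication rule and a
    low-coverage paralog merge, consensus-sequence motif extraction, Fitch
    parsimony habitat mapping, and a seeded gene-family birth-death simulator
    with ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
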