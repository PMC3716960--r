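Package: scquant
Title: Label-Free Spectral-Count Quantification of Two-Group Shotgun
    Proteomics Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free differential protein expression analysis
    by spectral counting in two pooled sample groups, as used in sperm
    proteomics studies of oxidative stress (reactive oxygen species
    positive versus negative semen). Aggregates peptide-spectrum matches
    to per-protein spectral counts, computes normalized spectral counts
    (NSC, optionally the length-corrected NSAF variant), forms
    between-group NSC ratios with explicit handling of group-exclusive
    proteins, classifies proteins by a fold-change rule, rolls protein
    lists up onto GO slim annotation maps with hypergeometric term
    enrichment, and simulates two-group spectral-count data with known
    ground truth for power analysis and pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
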