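Package: aidquant
Title: Quantitative Analyses for AID Mutants: BioID Differential
    Interactomes, Hypermutation Spectra and Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the quantitative analyses used to
    characterise activation-induced deaminase (AID) variants. Implements a
    four-method consensus procedure for calling differential protein-protein
    interactions from BioID spectral counts (fold enrichment over a control
    bait, global Z-scores on log fold changes, sliding-window local Z-scores
    on a ratio-intensity plot, and a negative-binomial Wald test with
    Benjamini-Hochberg correction), somatic-hypermutation spectrum analysis
    with WRC/GYW hotspot classification of Sanger clone sequences,
    fluctuation-assay mutation-frequency estimation, reporter-assay
    normalisation, and ChIP-qPCR percent-input quantification from standard
    curves. Ships matched synthetic-data generators with known ground truth
    so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
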