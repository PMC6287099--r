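Package: caprisweep
Title: Selective-Sweep and SNP-Desert Scans for Multi-Breed Resequencing
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for footprints of domestication and trait-driven
    breeding in multi-population resequencing cohorts, motivated by livestock
    (goat) breed panels. Implements SNP-desert detection from callable-length
    normalized SNP rates, pooled-heterozygosity (Hp) and windowed Fst scans
    with Z-score thresholds, cross-population extended haplotype homozygosity
    (XP-EHH), and the derived gene classifications (SNP-desert-associated,
    domestication-associated, and trait-associated genes) with QTL
    cross-referencing. Ships a forward-time Wright-Fisher cohort simulator
    with recombination, selection, and sequencing-depth emulation that
    generates every input format the pipeline consumes, with known ground
    truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
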