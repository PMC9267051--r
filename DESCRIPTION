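Package: genoprof
Title: Comparative Genome Profiling of Gene-Family Expansion, Repeat
    Landscapes and K-Mer Genome Size
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for comparative draft-genome profiling across plant
    genera: genome-size estimation from k-mer depth spectra (error/signal
    trough detection, homozygous-peak location, read- and spectrum-based
    estimators), transposable-element landscape scoring from domain-hit
    tables (GyDB clade assignment, per-clade accumulation ratios, per-Gb
    TE density), a pseudo-count log2 multiplication odds score over
    genus-by-superfamily gene-count matrices with expansion and
    contraction rankings, extraction of maximal single-genus
    ("multiplied") clusters from genus-labelled phylogenies, and
    domain-architecture classification (ribosome-inactivating protein
    type I/II typing, two-domain Venn partitioning).  Includes seeded
    synthetic-data generators with attached ground truth so every stage
    is testable without external data, and broom-style tidy(), glance()
    and ggplot2 autoplot() methods for the main result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
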