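Package: mutmotif
Title: Mutation Spectra, Trinucleotide Motif Enrichment and
    Forward-Mutation Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mutagenesis experiments in microbial
    genomes: filtering of per-isolate variant calls (allele-frequency,
    parent-strain and recurrence filters), pyrimidine-centered mutation
    spectra, a trinucleotide motif fold-enrichment statistic (for example
    gCn to A) with a one-sided Fisher's exact test and motif-attributable
    mutation load, and nonparametric statistics for forward-mutation
    plate assays (median frequencies with distribution-free confidence
    intervals, fold-changes, exact one-sided Mann-Whitney tests).
    Includes seeded generators for synthetic genomes, variant cohorts
    with known planted enrichment, and colony-count data, so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
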