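Package: hepnscape
Title: Gene-Neighborhood and Domain-Context Analysis of HEPN-Like Defense Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for characterising HEPN-like
    toxin domains and the defense systems they are embedded in. Predicts
    operons and divergons from annotated prokaryotic contigs using strand
    and intergenic-distance rules, clusters neighboring proteins by
    single-linkage on global-alignment identity and coverage, scans
    proteins and alignments for the Rx4-6H RNase active-site motif and
    classifies domains as catalytically active or inactive, assigns domain
    architectures from a user-supplied domain library, builds
    domain-context networks with fusion and gene-neighborhood edges, detects
    candidate toxin-antitoxin gene dyads, and tallies phyletic patterns and
    lineage-specific expansions. Ships a seeded synthetic-genome generator
    that plants operons, MNT-HEPN dyads, divergons, fusion proteins and
    motifs with machine-readable truth so every stage is testable without
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    igraph,
    generics,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
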