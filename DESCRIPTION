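Package: metacolor
Title: Metagenome Assembly and Profiling with Colored de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale de novo metagenome assembly on a canonical k-mer de
    Bruijn graph with locally sampled coverage heuristics, coupled with graph
    coloring against reference sequences. Colored coverage is demultiplexed
    through uniquely colored k-mers into per-reference abundance estimates,
    rolled up into taxonomic profiles by nearest-common-ancestor
    classification, and into gene-ontology term profiles. Includes a
    metagenome read simulator with power-law community abundances, paired
    reads, substitution errors and host contamination, plus truth-aware
    assembly evaluation (N50, breadth of coverage, misassembly
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
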