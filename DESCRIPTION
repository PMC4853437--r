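Package: scansoc
Title: Spatial Position, Dominance and Affiliative Network Structure from
    Scan-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing within-group spatial structure during feeding
    competition from instantaneous scan-sampling records of individually
    identified animals. Builds half-weight association indices and proximity
    networks from per-scan positions, tests for nonrandom association with a
    within-scan permutation of the association graphs, partitions the group
    into subgroups by Newman's leading-eigenvector modularity, computes
    dominance hierarchies (de Vries' h' linearity and modified David's
    scores) from dyadic agonistic records, and relates spatial frequencies
    near a monopolisable food patch to dominance and subgroup membership via
    permutation correlation, variance partitioning with semipartial r2, Mantel
    tests and MRQAP with double-semi-partialing. A seeded synthetic-data
    generator emulates the scan-sampling study design so every pipeline stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
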