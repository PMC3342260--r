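Package: mitonet
Title: Network Topology and Evolutionary Conservation of Mitotic Phenotype Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Network-level characterization of genes whose silencing perturbs
    mitosis. Builds signed, typed molecular interaction networks and their
    regulatory subnetworks, relates phenotypic trajectory (phenoprint)
    similarity to network proximity via Hausdorff distances and a
    sliding-threshold Wilcoxon procedure, tests evolutionary-conservation
    enrichment of hit genes and interactions with one-sided Fisher exact
    tests, measures giant-component robustness against targeted removals
    with a resampling null, and performs a signed-motif census with Boolean
    bistability classification, degree-preserving null models, and motif
    conservation analysis. A synthetic-data module generates inputs with the
    statistical structure the analysis assumes, so the full pipeline runs
    and is testable without any database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    ape,
    pracma,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
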