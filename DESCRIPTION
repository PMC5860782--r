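Package: stoichbal
Title: Stoichiometric Balance and Misinteraction Simulation for
    Interface-Resolved Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stoichiometric (dosage) balance of protein copy
    numbers in interface-resolved protein-protein interaction networks by
    solving a nonnegativity-constrained quadratic program for the closest
    balanced copy-number vector, and evaluates the consequences of imbalance
    with stochastic simulation. Includes chi-square and Jensen-Shannon
    distance metrics with resampling-based significance tests, a static-model
    random network generator with motif counting and rewiring, an exact
    Gillespie engine for competitive binary binding with specific and
    nonspecific (misinteraction) reactions, and a network-free rule-based
    engine for multi-site assembly used to model ARP2/3 complex formation and
    clathrin-coated vesicle assembly at the plasma membrane.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
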