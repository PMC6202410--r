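Package: symscales
Title: Scale-Resolved Reverse-Complement Symmetry Analysis of Genetic Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how strand symmetries of DNA sequences depend on
    genomic scale. Counts gapped-pattern observables and their frequencies,
    computes normalized cross-correlations z(l) between dinucleotides separated
    by a distance l, generates the reverse-complement symmetry groups S1-S4 and
    their closure sets, and summarises the strength of each symmetry per scale
    with a symmetry index I_S(l), from which the characteristic domain, cluster
    and macrostructure scales are estimated. Includes a three-level domain-model
    genome simulator (order-1 Markov domains, reverse-complemented chunks,
    concatenated macrostructures) with ground-truth scales for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
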