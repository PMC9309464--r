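Package: zosterosim
Title: Individual-Based Simulation of Hybridization-Mediated Evolutionary
    Rescue in Montane White-Eyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially and genetically explicit individual-based model of
    two hybridizing Zosterops (white-eye) species on a raster landscape of
    above-ground carbon (AGC). Diploid birds carry quantitative-trait alleles
    on chromosomes tagged with their founder species, survive, breed in
    faithful pairs, and disperse as juveniles under a greedy stochastic
    movement rule attracted to their AGC optimum. The package provides the
    landscape machinery (habitat classification, carrying capacities,
    fragment detection, habitat-change scenarios, a synthetic landscape
    generator), the annual simulation engine with replicate experiments over
    hybridization propensities and landscape scenarios, and the analysis
    metrics: population size, admixture heterozygosity (the percentage of
    extraspecific chromosomes in a species' gene pool) at global, patch and
    fragment level, trait means, and the regression of fragment
    heterozygosity on log fragment area.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    vctrs,
    readr,
    ggplot2,
    generics,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    jsonlite,
    optparse
Config/testthat/edition: 3
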