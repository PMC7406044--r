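Package: blockbal
Title: Covariate-Balanced Block Randomization for Experimental Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Divides a cohort of experimental units (e.g. laboratory animals)
    into blocks of predefined sizes, searches the space of unique block sets
    by uniform random sampling with duplicate rejection, and ranks candidate
    block sets by a covariate-balance score (maximal between-block mean
    difference normalized by the whole-set standard deviation, plus the
    maximal between-block difference in coefficient of variation, weighted
    and summed over covariates). Also counts unique block sets exactly,
    bounds the probability of missing top-ranked sets under partial search,
    minimizes physical-marker re-marking when blocks are split into housing
    subgroups, randomly allocates blocks to intervention groups, and ships
    the validation simulations (allocation-randomness and search-coverage
    experiments) together with a seeded synthetic-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
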