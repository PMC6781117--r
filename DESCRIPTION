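Package: mhcmate
Title: MHC-Based Mate-Choice Analysis for Closed Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing major histocompatibility complex (MHC) based
    mate-choice hypotheses in closed breeding populations such as captive
    crocodilian colonies. Provides individual genetic diversity indices
    (standardised heterozygosity, heterozygosity by locus, internal
    relatedness, mean d-squared, MHC heterozygosity), pair-level MHC
    compatibility measures (allele sharing, amino-acid distance and
    z-descriptor functional distance), pairwise relatedness estimators
    (Queller-Goodnight, Wang, Lynch-Ritland), a pond-stratified Monte-Carlo
    randomisation test of observed mate statistics against random-pairing
    nulls, a Poisson random-intercept model of male reproductive success,
    a Mendelian trio-consistency audit, and a pedigree-aware synthetic
    population generator with tunable female preference for ground-truth
    power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    lme4,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
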