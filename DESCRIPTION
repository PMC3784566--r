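Package: crisprflux
Title: Population Dynamics and Escape Genetics of CRISPR Immunity
    Against Conjugative Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying how bacterial populations evade
    the fitness downside of CRISPR-Cas immunity against beneficial conjugative
    plasmids. Implements end-point conjugation-rate estimation (gamma =
    T/(D*R)) and CRISPR-escape-fraction inference from mating count tables;
    Luria-Delbruck fluctuation-test summary statistics, a semi-stochastic
    simulator of CRISPR-loss mutant accumulation followed by plasmid transfer,
    and mutation-rate estimation by simulated mean matching; a six-population
    hybrid deterministic/stochastic model of conjugative plasmid spread in a
    CRISPR-immune population (Monod resource-limited growth, mass-action
    conjugation, Poisson mutation events); selection-coefficient estimation
    from serial-transfer competition trajectories via logit-linear regression;
    and a parser, classifier and tally for CRISPR-escape genotypes including
    large locus-deletion span arithmetic. Seeded synthetic-data generators
    emulate every input format so all analyses are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
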