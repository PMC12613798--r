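Package: thermotk
Title: Temperature Dependence of Toxicokinetic Rate Constants in Aquatic
    Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how temperature affects uptake and
    elimination rate constants of organic chemicals in aquatic ectotherms.
    Implements the linearized Arrhenius regression of ln(k) on inverse
    temperature with full coefficient statistics (standard errors,
    coefficients of variation, confidence intervals, R-squared, p-values),
    allometric quarter-power mass normalization, one-compartment
    toxicokinetic simulation and rate-constant estimation, data-treatment
    rules for compiled literature datasets (duplicate averaging at rounded
    temperatures, life-stage-aware mass imputation, minimum-temperature
    filtering), hydrophobicity- and species-stratified fits with a nested
    F-test of slope equality, assessment of the temperature independence
    of the bioconcentration factor, and a seeded synthetic-data generator
    emulating multi-taxon rate-constant compilations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
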