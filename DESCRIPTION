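Package: reactigen
Title: Genetic Analysis of Ethogram-Derived Behavioral Reactivity Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of behavioral reactivity
    in livestock scored from a handling-test ethogram. Derives responsiveness,
    vocalization and handling-duration traits from coded observation sessions;
    applies standard SNP-chip quality control; builds the VanRaden (method 1)
    genomic relationship matrix; fits single-trait, repeatability and two-trait
    animal models by Gibbs sampling to estimate variance components,
    heritabilities and genetic correlations; back-solves genomic breeding
    values into per-SNP effects for association mapping with chromosome-wise
    significance thresholds based on the effective number of independent
    chromosome segments; and simulates genotypes, phenotypes and ethogram
    sessions with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    MASS,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
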