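Package: eemkit
Title: Electronegativity Equalization Method Charges, Parameterization and
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calculates empirical partial atomic charges with the
    electronegativity equalization method (EEM) from 3D structures in MDL
    SDF (V2000) format, calibrates EEM parameter sets (kappa plus per
    atom-type A and B) against reference quantum-mechanical charges by two
    algorithms (linear regression with a kappa scan, and differential
    evolution hybridized with derivative-free local minimization), and
    validates parameter sets through coverage and charge-quality
    statistics. Includes a synthetic-fixture generator producing molecules
    with self-consistent reference charges from known ground-truth
    parameters, and a command-line interface over all modes.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
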