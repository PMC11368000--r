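Package: cardiopop
Title: Population-Based In Vitro Cardiotoxicity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-based cardiotoxicity screening with human
    iPSC-derived cardiomyocytes: feature extraction from calcium-flux traces
    (beat rate, decay-to-rise ratio, asystole), plate quality control and
    variance decomposition, hierarchical Bayesian random-effects Hill
    concentration-response modeling with donor random effects, points of
    departure (EC05/EC10/EC95) for median and sensitive individuals,
    toxicodynamic variability factors, ToxPi multi-endpoint ranking,
    probabilistic in vitro-to-in vivo extrapolation to margins of exposure,
    and structure-activity analysis with permutation-calibrated ridge
    prediction. Includes a synthetic-study generator emulating the full
    screening design for testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    stats,
    utils,
    ggplot2,
    lme4,
    jsonlite,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
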