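Package: psequate
Title: Score Equating for Health Scales with Leunbach's Power-Series Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equates the total scores of two patient-reported outcome scales
    using Leunbach's power-series distribution model. Score parameters are
    estimated by conditional maximum likelihood via iterative proportional
    fitting, model fit is assessed with three tests (conditional likelihood
    ratio, Goodman-Kruskal gamma, and a count of persons with significantly
    discrepant subscores) with parametric-bootstrap p-values, and score
    crosswalk tables are produced by direct (common-person) and indirect
    (common-scale) equating with a bootstrap Standard Error of Equating.
    Includes a synthetic-data generator for polytomous scale scores driven by
    a shared latent trait, with controlled model violations for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
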