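Package: occutrend
Title: Occupancy Trends from Opportunistic Records and Trait-Based
    Comparative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates species occurrence trends from opportunistic
    (unstructured) biological records using Bayesian occupancy-detection
    models with a list-length effort covariate, then relates the trends to
    species traits with phylogenetically informed regression. Detection
    histories are built from unique site-by-date visits, poorly sampled
    sites are filtered out, and per-species occupancy models are fitted by
    MCMC, yielding posterior draws of annual occupancy and of its linear
    trend. Trait effects are estimated by phylogenetic generalized least
    squares with maximum-likelihood Pagel's lambda inside a
    posterior-resampling loop that propagates trend uncertainty into the
    trait coefficients. A synthetic-data generator with known ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
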