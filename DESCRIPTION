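Package: popgrowth
Title: Growth Analysis and Early Selection for Clonal Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term clonal progeny trials of
    fast-growing trees, built around annual diameter and height
    remeasurements of direct and reciprocal poplar crosses. Derives
    stem traits (height-to-diameter ratio, basal area, form-factor
    volume), computes mean and periodic annual volume increments and
    detects the quantitative maturity (rotation) age where the two
    cross, decomposes trait correlations with volume into direct and
    indirect path coefficients over pooled age windows, scores age-age
    correlations for early-selection efficiency, and ranks and selects
    clones under a survival filter and a fixed selection rate. Includes
    a seeded trial simulator with logistic growth, clone-level random
    effects, measurement noise and mortality, so every stage can be
    exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
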