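Package: matchrisk
Title: Match Exposure and Recurrent Injury Risk in Professional Team Sport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling recurrent time-loss injury risk as a function of
    rolling match-exposure workloads in multi-team longitudinal cohorts.
    Provides validated CSV exchange for roster, match, training and injury tables;
    rolling 12-month and 30-day exposure covariates (match counts and full-game
    equivalents); construction of gap-time risk intervals on an exposure-hour
    axis; proportional-hazards fits with zero, one (player) or two nested
    (team/player) log-normal frailties estimated by penalized partial likelihood
    with a Laplace-approximate marginal likelihood; two-standard-deviation
    hazard ratios, cubic exposure-response curves and exposure-quartile
    interactions; magnitude-based-inference classification of hazard ratios;
    model comparison by likelihood ratio, AIC and BIC; and a calibrated
    synthetic cohort generator for validation studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    survival,
    tidyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
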