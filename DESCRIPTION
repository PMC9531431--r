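Package: qolsurv
Title: Quality of Life with Survival Outcomes in Oncology Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of quality-of-life (QOL) endpoints
    truncated by death in two-arm oncology trials. Provides a four-scenario
    trial simulator (exponential-type overall survival with a no-death
    plateau, terminal decline of QOL before death, latent potential outcomes
    under both arms) and the analysis methods used to summarise QOL in the
    presence of death under the estimand framework: the prioritized composite
    score with its combined distribution curve, quantiles and generalized
    pairwise comparisons (win ratio, net benefit); time-to-deterioration
    analysis; semi-competing-risk analysis (cumulative incidence, Gray's
    test, Fine-Gray model); survivor analysis; terminal-decline (backward
    from death) summarisation with a changepoint fit; MMRM; and the survivor
    average causal effect (true value from potential outcomes and a
    survival-probability-weighted estimator). Plot-data builders produce
    testable coordinates for each graphical display.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cmprsk,
    nlme,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
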