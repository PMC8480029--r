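Package: priorsim
Title: Monte Carlo Evaluation of Background Knowledge from Preceding
    Studies in Variable Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation machinery for studying how the quality of variable
    selection in earlier ("preceding") studies propagates into the
    background knowledge assumed by a later study.  Generates synthetic
    cohort data from a calibrated linear data-generating mechanism with a
    Gaussian-copula (NORTA) covariate model, applies univariable
    prescreening or AIC-based backward elimination within each preceding
    study, combines the selected variables across studies with k-of-3
    evidence rules, and scores the resulting "known predictor" sets with
    six performance indicators (model selection frequency, true positive
    rate, false positive and false negative rates, descriptive model
    selection frequency, and mean squared prediction error) over a
    30-scenario grid of preceding-study sample sizes.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
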