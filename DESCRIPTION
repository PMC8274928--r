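Package: vasofit
Title: Arterial Pressure-Area Modelling for Ex Vivo Inflation-Extension Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing ex vivo arterial inflation-extension
    experiments. Fits the three-parameter arctangent (Langewouters)
    pressure-area model to lumen areas derived from replicate ultrasound
    diameter measurements, derives analytic compliance and distensibility
    curves and their maxima, compares curves between age groups with nested
    extra-sum-of-squares F-tests, compares summary metrics with two-way
    ANOVA and Bonferroni-adjusted post-hoc contrasts, aggregates layered
    histomorphometry (intima-media thickness and stain area percentages)
    with thickness weighting and mixed-model ANOVA, and generates synthetic
    inflation and histology datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    ggplot2,
    lmerTest,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
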