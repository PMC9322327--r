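Package: traitenv
Title: Trait-Environment-Performance Analysis for Nested Crop Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models crop performance as a function of plant traits, soil and
    climate environment, genotype (variety), and their interactions in a
    three-level nested linear mixed model (farm / plot / subplot random
    intercepts). Provides the polynomial-interaction term graph with
    marginality (containment) relations, restricted maximum likelihood fits
    via 'lme4', an in-package Kenward-Roger small-sample adjustment, type-II
    marginality ANOVA, marginality-respecting backward elimination,
    AIC comparison of collinearity-driven alternative predictor sets, and the
    framework's namesake outputs: environment-dependent trait-performance
    slopes per variety, quadratic response surfaces with stationary-point
    classification, and marginal/conditional R-squared decomposition. A
    synthetic-data generator reproduces the 9-farm x 5-variety x 3-subplot x
    3-plant field design for testing and power analysis.
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
    lme4,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    lmerTest,
    pbkrtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
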