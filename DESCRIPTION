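Package: tmlevim
Title: Targeted Variable Importance for Dimension Reduction of Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks and screens candidate variables in high-dimensional
    expression-style datasets by a targeted maximum likelihood estimate of each
    variable's adjusted marginal effect on a continuous outcome. A first-stage
    machine-learning fit of the outcome is updated along a clever-covariate
    fluctuation driven by a fitted confounding mechanism E(A|W), yielding a
    doubly robust effect estimate with influence-curve-based standard errors
    and p-values. Includes seeded simulation designs with exchangeable-cluster
    and general correlation structure, downstream-prediction benchmarking
    (L2 risk, true/false positive recovery), broom-style tidiers, ggplot2
    autoplot methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
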