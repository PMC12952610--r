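Package: gravityflow
Title: Gravity-Model Analysis of Settlement-Level Internal Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling long-term internal migration between
    settlements with unconstrained (total-constrained) spatial interaction
    models. Predicts origin-destination flows from settlement populations
    and pairwise distances under power or exponential distance decay,
    calibrates the population-scaling and distance-decay parameters by grid
    search against intercensal census stocks, and validates fits with MAE,
    MAPE and standardised RMSE plus a regional relative-difference
    benchmark. Includes Euclidean and road-network distance matrices with
    nearest-node snapping, the Riley terrain ruggedness index with
    settlement-level quantile classification, flow-network exports and
    TRI-group migration statistics, and a synthetic settlement-system
    generator (rank-size populations, ridge DEMs, Gabriel road graphs,
    Poisson gravity flows) with known ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
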