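Package: mediaopt
Title: Design of Experiments, Surrogate Models and Evolutionary
    Optimization for Culture Media and Bioprocess Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable workflow for data-driven optimization of culture
    media and bioprocess formulations from tabular experimental data.
    Generates experimental designs (full factorial, central composite,
    Box-Behnken, Latin hypercube, random), performs automated data quality
    checks and variable typing, runs a nine-algorithm regression spot-check
    with repeated k-fold cross-validation, and couples the selected
    surrogate models to single- and multi-objective evolutionary
    optimizers (GA, PSO, NSGA-II, SMS-EMOA) with min-max fitness
    normalization, penalty constraints and hypervolume-based selection.
    Includes solution filtering, original-versus-optimized evaluation and
    synthetic benchmark generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    FNN,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
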