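Package: fnro
Title: Hybrid Gene Selection with Statistical Filters and Nuclear Reaction Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Selects compact, discriminative gene subsets from high-dimensional
    expression matrices with a two-stage hybrid strategy: univariate and
    multivariate statistical filters (F-score / ANOVA F, information gain,
    ReliefF, mRMR) reduce thousands of genes to a candidate pool, then the
    Nuclear Reaction Optimization metaheuristic (a population search
    alternating fission exploration and fusion exploitation with Levy-flight
    escapes) refines the pool to a fixed-size subset that maximizes linear-SVM
    classification accuracy under leave-one-out cross-validation. Includes
    preprocessing (mean imputation, per-gene Z-scoring, label encoding), a
    synthetic-data generator with planted informative genes for end-to-end
    validation, repeated-run experiment orchestration with confidence
    intervals, broom-style tidiers, and ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
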