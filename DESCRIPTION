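Package: metoncokit
Title: Metabolic-Network Features and Tumor-Fitness Classification for
    Constraint-Based Cancer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives biochemical, topological and flux-dynamic features for
    every gene of a constraint-based metabolic model, assigns ternary
    tumor-fitness labels (differential expression, copy-number gain/loss,
    survival impact) from omics tables via explicit threshold rules, trains a
    random-forest classifier per cancer context, and reports accuracy,
    Gini feature importances and feature-target correlation directions.
    Includes flux balance analysis with total-flux minimization and
    gene-deletion screens, shortest-path epicenter scores on the directed
    metabolite graph, leakage-safe cross-validation with class rebalancing,
    permutation-null significance, and a seeded synthetic-fixture generator
    producing toy metabolic models and omics tables with planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    optparse,
    pracma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
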