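Package: fsbrr
Title: Filter Feature Selection by Approximate Redundancy Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mutual-information-based filter feature selection for
    high-dimensional biomedical classification tables. Features are scored
    against the class attribute by symmetric uncertainty (normalized
    information gain), irrelevant features are dropped by a threshold, and
    approximately redundant features are pruned by pairwise feature-feature
    relevance under two delta/alpha-gated rules applied in descending
    relevance order. Includes a repeated stratified k-fold cross-validation
    harness with random forest, 1-nearest-neighbour and linear-SVM
    classifiers, a composite accuracy/sparsity performance score, a seeded
    synthetic-data generator with planted informative, duplicated and
    irrelevant features, readers for CSV and ARFF feature tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
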