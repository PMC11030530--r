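Package: scbench
Title: A Desk-Scale Living Benchmark Framework for Single-Cell Analysis Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A component model for benchmarking single-cell analysis methods:
    tasks are decomposed into datasets, methods, and metrics; a runner
    evaluates every method on every dataset with every metric; scores are
    anchored to positive/negative control ("baseline") methods so that the
    optimum maps to 1 and random performance to 0, then averaged and ranked
    per dataset. Ships seven concrete tasks (label projection, denoising via
    molecular cross-validation, 2D dimensionality reduction, batch
    integration across matrix/embedding/graph outputs, spatial
    deconvolution, modality matching, and cell-cell communication) exercised
    entirely on seedable synthetic data with planted ground truth, plus an
    annotated cell-by-gene container with h5ad and Matrix Market
    serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    glmnet,
    pracma,
    cluster,
    igraph,
    rhdf5,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
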