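Package: o2plsr
Title: Two-Way Orthogonal Partial Least Squares for Paired Omics Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symmetric integration of two sample-matched omics data matrices
    with Two-way Orthogonal Partial Least Squares (O2PLS). Decomposes each
    block into a joint part shared between the blocks, a block-specific
    orthogonal part and residual noise, provides two-way prediction through
    the inner relation between joint scores, an inner-relation R-squared
    grid search combined with k-fold prediction error for choosing the
    numbers of components, explained-variation summaries, a calibrated
    simulation engine for studying loading-estimate accuracy, and the
    preprocessing steps (Box-Cox transform, mean centering,
    expression-level and interquartile-range filtering) commonly applied
    before integrating metabolomic and transcriptomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    callr,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
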