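Package: sidemc
Title: Matrix Completion with Side Information via Stochastic Linearized ADMM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Completes partially observed numeric matrices, such as patient by
    diagnostic-criterion phenotype tables, by coupling a nuclear-norm
    regularized completed matrix with a sparse bilinear interaction model
    built from row-side and column-side feature matrices (for example
    genotype dosages and criterion-criterion correlations).  The convex
    objective is optimized by a linearized alternating direction method of
    multipliers and by a stochastic variant that samples rows of the implicit
    Kronecker constraint operator, so the full operator is never formed.
    Includes a synthetic benchmark generator, a cross-validation protocol for
    the regularization weights, an experiment harness reporting relative mean
    squared error on missing entries, and an out-of-matrix bilinear predictor
    for new row or column entities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    parallel,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
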