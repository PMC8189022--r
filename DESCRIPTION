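Package: sunnies
Title: Shapley Decomposition of Non-Linear Dependence Measures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-independent global feature attribution by Shapley
    decomposition of non-linear dependence measures. Implements the
    empirical distance correlation, affine-invariant distance correlation,
    Hilbert-Schmidt independence criterion and coefficient of multiple
    correlation as cooperative-game characteristic functions, with exact,
    Monte Carlo and blockwise Shapley solvers. Provides the attributed
    dependence on labels (ADL), predictions (ADP) and residuals (ADR)
    diagnostic workflows with bootstrap intervals, seeded simulators for
    four reference data-generating processes, and a command-line
    interface with JSON result records.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
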