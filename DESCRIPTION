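Package: revs
Title: Regression with Empirical Variable Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variable selection for multiple linear regression with many
    correlated predictors. An exact per-level best-subset search (exhaustive
    enumeration or residual-sum-of-squares-bound branch-and-bound) finds the
    best k-variable model at every level k, predictors are ranked by how often
    they appear across those level-best models, and a nested model series is
    built in rank order and compared by AIC and delta-AIC, with explicit
    handling of ranking ties (alternative models are fitted when the best-model
    boundary splits a tie group). Includes the standard comparators (full-model
    regression, p-value and AIC-criterion stepwise selection), split-sample
    hold-out validation with honest R-squared and residual sum of squares, a
    seeded generator of correlated synthetic datasets, CSV input/output, report
    writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
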