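Package: covforest
Title: Random Forests for Conditional Covariance Matrix Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric covariance regression with random forests.
    Trees are grown with a splitting rule that maximizes the heterogeneity
    of the sample covariance matrix of a multivariate response between
    child nodes; conditional covariance matrices are estimated from the
    out-of-bag nearest-neighbour set of each observation (the bag of
    observations for prediction). Includes a heuristic nodesize tuning
    procedure based on the stability of out-of-bag estimates, permutation
    tests for the global and partial effects of covariates on the
    conditional covariance matrix, fit-the-fit variable importance via a
    multivariate regression forest with a Mahalanobis splitting rule,
    heteroscedastic multivariate normal data generators for validation,
    and accuracy metrics (correlation and standard-deviation mean absolute
    errors, Stein's loss).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
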