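Package: cvbias
Title: Bias-Variance Decomposition of Cross-Validation Error Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo framework for comparing resampling estimators of a
    classifier's misclassification error. Implements quadratic discriminant
    analysis, six cross-validation schemes with equalized retraining budgets
    (leave-one-out, repeated n/2-fold and 10-fold CV, and their bootstrap
    cross-validation counterparts), true conditional error measured against a
    super-population holdout, and the full decomposition of mean squared error
    into within-run variance and mean squared bias, including the spread/mean
    split of the squared bias. Includes a synthetic two-class Gaussian data
    generator, a study driver reproducing the bias-variance trade-off tables,
    and a runner for user-supplied feature tables with t-statistic feature
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
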