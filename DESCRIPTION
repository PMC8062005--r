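Package: sparsepois
Title: Best-Subset Poisson Regression via Mixed-Integer Quadratic Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cardinality-constrained (best-subset) Poisson regression solved
    to proven optimality. The concave Poisson log-likelihood is replaced by a
    piecewise-linear envelope of tangent lines, turning subset selection into
    a mixed-integer quadratic optimization problem that an exact solver can
    certify. Includes five tangent-selection strategies (equally spaced, two
    greedy area/gap rules, an adaptive greedy rule driven by the empirical
    predictor distribution, and simultaneous optimization of the total
    approximation area), forward-stepwise and L1-regularized comparison
    selectors, a synthetic benchmark generator with autoregressive covariate
    correlation, and evaluation metrics for count prediction and support
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    reticulate,
    nloptr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
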