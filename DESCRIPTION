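Package: poisridge
Title: Ridge and Almost Unbiased Ridge Estimation for Poisson Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum likelihood and biased (ridge-type) estimation for the
    Poisson regression model under multicollinearity. Implements the Poisson
    ridge regression estimator (PRRE), the almost unbiased Poisson ridge
    estimator (AUPRRE) and its modified form (MAUPRRE), together with their
    closed-form bias, covariance and mean squared error expressions in the
    canonical (eigen) coordinate system, data-driven ridge-parameter
    selectors, numeric checkers for the estimators' dominance conditions, and
    a Monte Carlo engine for comparing the estimators' empirical MSE and bias
    under controlled degrees of collinearity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
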