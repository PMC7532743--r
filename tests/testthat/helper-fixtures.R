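# Shared fixture builders: everything is generated in code at test time.

# A fitted Poisson dataset with collinear regressors and its canonical form.
make_fitted_fixture <- function(n = 50, q = 3, rho = 0.9, seed = 1,
                                beta = rep(1 / sqrt(q), q), intercept = 0.2,
                                add_intercept = TRUE) {
  set.seed(seed)
  X <- generate_regressors(n, q, rho)
  y <- generate_response(X, beta, intercept)
  Xfit <- if (add_intercept) cbind(`(Intercept)` = 1, X) else X
  ds <- count_dataset(y, Xfit)
  fit <- fit_poisson_mle(ds)
  cf <- canonical_decompose(ds, fit)
  list(ds = ds, fit = fit, cf = cf, beta = beta, intercept = intercept)
}

# Random positive eigenvalues and nonzero canonical coefficients.
random_canonical <- function(p = 4, seed = 1) {
  set.seed(seed)
  list(lambdas = sort(exp(stats::runif(p, -2, 3)), decreasing = TRUE),
       alpha = stats::runif(p, 0.3, 2) * sample(c(-1, 1), p, replace = TRUE))
}
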