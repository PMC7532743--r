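---
title: "Methods: ridge-type shrinkage for Poisson regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ridge-type shrinkage for Poisson regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the estimators, the numerical
choices, and the design decisions behind `poisridge`, including known
limitations. Code chunks are illustrative and not evaluated when the vignette
is built; every empirical claim made here is computed by the package's test
suite or by `scripts/acceptance.R`.

## Model and assumptions

The package fits the Poisson generalized linear model with canonical log link:
independent counts `y_i ~ Poisson(mu_i)` with `log(mu_i) = x_i' beta`. The
design matrix must have full column rank and more rows than columns; an
intercept column of ones is detected automatically by `count_dataset()` and
treated as a coefficient like any other (see "Intercept handling" below).

The maximum likelihood estimator is computed by iteratively reweighted least
squares (IRLS, equivalently Fisher scoring):

```
beta^(t+1) = (X' W X)^{-1} X' W z*,  W = diag(mu_hat),
z*_i = log(mu_hat_i) + (y_i - mu_hat_i) / mu_hat_i,
```

iterated to convergence. At the converged weights, the spectral decomposition
`X' W X = Q Lambda Q'` defines the *canonical form*: `Z = X Q`,
`alpha = Q' beta_MLE`, eigenvalues `lambda_1 >= ... >= lambda_p > 0`. All
shrinkage estimators and all MSE theory are expressed in these coordinates.

## Estimators

Each estimator multiplies the canonical MLE coordinates componentwise by a
shrinkage factor `f_j(k)` that equals 1 at `k = 0`:

- **PRRE** (ordinary Poisson ridge): `f_j = lambda_j / (lambda_j + k)`,
  equivalently `(X'WX + kI)^{-1} X'WX beta_MLE`.
- **AUPRRE** (almost unbiased): `f_j = 1 - k^2/(lambda_j + k)^2`, the
  one-step bias correction of the PRRE. Its bias, `-k^2/(lambda_j+k)^2
  alpha_j`, is the square of the PRRE's relative bias, hence "almost
  unbiased".
- **MAUPRRE** (modified almost unbiased): `f_j = (1 - k^2/(lambda_j+k)^2)
  (1 - k/(lambda_j+k))`, composing the bias-corrected factor with a further
  ridge-style factor. It shrinks hardest of the three and wins on MSE under
  severe collinearity, at the cost of the largest bias.

Bias, covariance, and MSE follow from the factor algebra: for shrinkage
factor `f_j`, the canonical bias is `(f_j - 1) alpha_j`, the canonical
covariance is `diag(f_j^2 / lambda_j)` (conditional on the converged
weights), and the scalar MSE is `sum_j f_j^2/lambda_j + sum_j (f_j-1)^2
alpha_j^2`. `matrix_mse()` returns the original-scale matrix form
`Q (C + b b') Q'`, and the test suite verifies `scalar_mse()` equals its
trace to 1e-10 on thousands of random instances.

### A note on one printed closed form

Closed-form summation expressions for these MSEs circulate in the applied
literature. For PRRE and AUPRRE the standard printed summations agree exactly
with the trace of the matrix MSE, and the package's tests verify this. A
commonly printed MAUPRRE scalar-MSE summation, however, is internally
inconsistent: evaluated at `k = 0` it reduces to `sum(1/lambda_j^3)` rather
than the MLE value `sum(1/lambda_j)`, because its variance term carries an
extra squared ridge ratio. `scalar_mse(ti, "MAUPRRE")` therefore uses the
trace-based quantity as authoritative; the literal summation remains
available behind `as_printed = TRUE` so the discrepancy can be inspected, and
a test asserts the two diverge. A similarly inconsistent printed form of the
MAUPRRE bias exists; the package derives all biases from the factor algebra
instead, which guarantees the decomposition `MSE = covariance + bias bias'`
by construction.

## Ridge-parameter selectors

All selectors use the dispersion-style estimate
`sigma2_hat = sum((y_i - mu_hat_i)^2) / (n - q + 1)`, where `q` is the number
of **non-intercept** regressors. The `q + 1`-vs-`q` convention matters: the
denominator is `n - q + 1`, not `n - p`, matching the convention under which
these selectors were proposed; with an intercept and `q` regressors this is
`n - (p - 1) + 1`. The selectors are

- `k_TO = median(sigma2_hat / alpha_j^2)`;
- `k_q1`–`k_q4`: mean, median, max, and geometric mean (over all `p`
  components) of `(sigma2_hat + sqrt(sigma2_hat + alpha_j^2 lambda_j)) /
  alpha_j^2`.

These components are themselves motivated by the componentwise MSE-optimal
ridge value for the bias-corrected estimator,
`k_j = (1 + sqrt(1 + alpha_j^2 lambda_j)) / alpha_j^2` (at unit dispersion),
which `optimal_k_components()` exposes; a test verifies it is a stationary
point of the componentwise AUPRRE MSE by central differences. The aggregate
ordering `k_q3 >= k_q1 >= k_q4` (max ≥ mean ≥ geometric mean) is also tested.

## Dominance theory

`theorem_thresholds()` returns, per canonical component, the `k` range over
which the AUPRRE's componentwise MSE beats the PRRE's (a lower threshold
`k* = (3 - lambda alpha^2 + sqrt((3 + lambda alpha^2)^2 + 4 lambda
alpha^2)) / (4 alpha^2)`) and beats the MLE's (an upper threshold
`(2 lambda + lambda sqrt(2 (1 + lambda alpha^2))) / (lambda alpha^2 - 1)`
when `lambda alpha^2 > 1`, infinite otherwise — i.e. AUPRRE dominates the MLE
at every `k` when `lambda alpha^2 <= 1`). Tests verify the MSE difference
changes sign exactly at these thresholds on hundreds of random instances.
`mauprre_dominance_condition()` implements the quadratic-form certificate for
matrix-MSE dominance (the bias vector `b` must satisfy `b' D^{-1} b <= 1`
where `D` is the covariance improvement); when the certificate fires, the
tests confirm the matrix-MSE difference is positive semidefinite.

## The simulation engine

`simulation_design()` / `run_cell()` implement a factorial Monte Carlo
experiment. Defaults encode the study conditions used throughout the
collinearity literature, and we keep them deliberately:

- **Slopes** `beta_j = 1/sqrt(q)` so that `sum(beta^2) = 1`. This
  normalization makes MSE comparable across `q` and is enforced (a custom
  `beta` must satisfy it). The intercept is 0 by default and is fitted.
- **Regressors** `x_ij = sqrt(1 - rho^2) z_ij + rho z_{i,q+1}` with i.i.d.
  standard normal `z`. Every column has unit population variance and every
  pair of columns has population correlation `rho^2`, so `rho = 0.99` yields
  pairwise correlation 0.98 — severe but realistic collinearity, one common
  latent factor. The acceptance tests verify the realized correlation at
  `n = 100000` is within 0.01 of `rho^2`. *Realism limits*: the construction
  produces exactly one compound-symmetric correlation structure; it cannot
  represent heterogeneous correlations, heavy-tailed regressors, or more than
  one collinear cluster. It is a stress-test instrument, not a model of any
  particular dataset.
- **Design redraw**: `X` is redrawn every replicate (`redraw_X = TRUE`), so
  the Monte Carlo MSE is unconditional; set `redraw_X = FALSE` for the
  conditional (fixed-design) experiment.
- **Metrics**: empirical MSE `(1/R) sum_r ||beta_hat_r - beta||^2` and
  absolute bias `(1/R) sum_r sum_j |beta_hat_rj - beta_j|`, intercept
  included by default (`mse_scope = "slopes"` excludes it). The Monte Carlo
  standard error of the MSE is reported as `mc_se_of_mse`.
- **Failures**: replicates whose IRLS fit does not converge, or whose
  canonical coefficients degenerate, are redrawn (capped at 10 attempts) and
  counted in `n_failed`, so reported averages are over exactly `R`
  convergent fits.
- **Problem sizes**: the package's own experiments and tests use
  `rho` in {0.80, 0.90, 0.95, 0.99}, `q` in {3, 6}, `n` from 25 to 400, and
  `R` up to 1000 — small enough to run in seconds-to-minutes, large enough
  that severe collinearity genuinely degrades the MLE.

`design_grid()` derives per-cell seeds from a master seed by a fixed counter
scheme (`master + 104729 * (cell - 1) mod 2^31 - 1`) so that cells are
reproducible and order-insensitive, and all derived seeds stay below `2^31`.

## Numerical choices

- **IRLS initialization**: slopes start at 0 and the intercept (when present)
  at `log(mean(y) + 1e-8)`, a standard safe start for log-link models.
- **Convergence**: relative change in deviance below `tol` (default `1e-8`),
  at most `max_iter = 100` iterations; non-convergence is flagged, not
  silently accepted, and the simulation engine treats it as a failed
  replicate.
- **Mean flooring**: fitted means are floored at `1e-12` (with a warning) so
  the working weights and adjusted response stay finite when a linear
  predictor drifts very negative mid-iteration.
- **Eigenvector sign convention**: each column of `Q` is flipped so its
  largest-magnitude entry is positive. Eigenvectors are only defined up to
  sign; fixing it makes `alpha`, canonical outputs, and CSV artifacts
  byte-reproducible across platforms.
- **Exactness of the canonical coordinates**: shrinkage is applied to
  `alpha = Q' beta_MLE` rather than to `Lambda^{-1} Z' W z*`. The two agree
  only up to IRLS tolerance (they are equal at the exact fixed point), and
  using `alpha` makes the `k = 0` collapse to the MLE exact to machine
  precision — a property the tests assert at 1e-10. The fixed-point form is
  retained in the canonical object (`gamma_mle`) and a test checks the two
  agree to 1e-6 on converged fits.
- **Condition number**: reported as `max(lambda)/min(lambda)` of the weighted
  cross-product, i.e. on the information scale at the converged weights.

## Intercept handling

`count_dataset()` detects a constant-ones column and records `q = p - 1`
regressors. The intercept is shrunk along with the slopes (it participates in
the canonical decomposition); this matches the convention under which the
estimators and selectors above were proposed, where the study designs center
the truth at intercept 0. Users who prefer not to shrink the intercept can
center their regressors and fit without an intercept column. The selector
denominator uses `q`, never `p`, as described above.

## Command-line interface

`exec/poisridge` exposes `fit`, `simulate`, `curves`, and `fixture`
subcommands over the exported functions `cmd_fit()`, `cmd_simulate()`,
`cmd_curves()`, and `make_fixture()`. All outputs are plain CSV/JSON;
`cmd_simulate()` validates its JSON config strictly (unknown keys are
errors), and fixtures carry a JSON sidecar recording the generating
parameters. Exit codes: 0 success, 2 usage error, 3 input error, 4 runtime
failure.

## Known limitations

- The standard errors are conditional on the converged IRLS weights and
  ignore the variability of the data-driven `k`; they understate the
  unconditional uncertainty of selector-based fits. The Monte Carlo engine is
  the honest instrument for unconditional comparisons.
- The MSE theory treats `alpha` and `lambda` as known; plugging in estimates
  (as `theory_input(cf$lambdas, cf$alpha, k)` does) gives an empirical-Bayes
  style approximation whose quality degrades exactly when shrinkage matters
  most.
- The generator covers only the single-latent-factor correlation structure
  described above.
- Under extreme collinearity with very small `n` (e.g. `q = 6`, pairwise
  correlation 0.98, `n = 25`), the distribution of the MLE's squared error is
  extremely heavy-tailed; Monte Carlo MSE estimates for the MLE at such cells
  are unstable even at `R = 1000` and should be read alongside
  `mc_se_of_mse`. The shrinkage estimators do not share this instability.
- No offsets, weights, or non-canonical links are supported.
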