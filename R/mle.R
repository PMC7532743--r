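#' Poisson deviance
#'
#' @param y observed counts.
#' @param mu fitted means (all > 0).
#' @return 2 * sum(y log(y/mu) - (y - mu)), with the y log y term taken as 0
#'   when y = 0.
#' @keywords internal
poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Fit a Poisson regression model by iteratively reweighted least squares
#'
#' Maximum likelihood for the log-link Poisson model mu_i = exp(x_i' beta),
#' by Fisher scoring: at each iteration the working (adjusted) response
#' z_i = eta_i + (y_i - mu_i)/mu_i is regressed on X with weights mu_i,
#' beta <- (X'WX)^{-1} X'W z. Convergence is declared when the relative
#' change in deviance falls below \code{tol}.
#'
#' Initialization: all coefficients zero, except that an intercept column of
#' ones starts at log(mean(y) + 1e-8) so the first weights are finite even
#' when y contains zeros. Fitted means are floored at 1e-12 inside the weight
#' matrix (with a warning) to prevent numerical collapse on extreme designs.
#'
#' @param data a \code{\link{count_dataset}}.
#' @param tol relative deviance-change tolerance (default 1e-8).
#' @param max_iter maximum number of scoring iterations (default 100).
#' @return An object of class \code{poisson_mle}: list with \code{beta_hat},
#'   \code{mu_hat}, \code{weights} (the floored mu used as W), \code{z_star}
#'   (adjusted response at convergence), \code{converged}, \code{n_iter},
#'   \code{deviance}.
#' @export
fit_poisson_mle <- function(data, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "count_dataset"))
  if (!(is.numeric(tol) && length(tol) == 1 && tol > 0)) stop("`tol` must be a positive scalar")
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  y <- data$y
  X <- data$X
  n <- data$n
  p <- data$p

  beta <- rep(0, p)
  if (data$has_intercept) beta[1] <- log(mean(y) + 1e-8)

  dev_old <- Inf
  converged <- FALSE
  floored <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    if (any(!is.finite(mu))) {
      stop("IRLS diverged: non-finite fitted means at iteration ", it)
    }
    w <- pmax(mu, 1e-12)
    if (any(mu < 1e-12)) floored <- TRUE
    z <- eta + (y - mu) / w
    A <- crossprod(X * sqrt(w))
    b <- crossprod(X, w * z)
    beta_new <- tryCatch(drop(solve(A, b)),
                         error = function(e) stop("singular weighted design in IRLS: ", conditionMessage(e)))
    beta <- beta_new
    mu_new <- exp(drop(X %*% beta))
    if (any(!is.finite(mu_new))) {
      stop("IRLS diverged: non-finite fitted means at iteration ", it)
    }
    dev <- poisson_deviance(y, pmax(mu_new, 1e-300))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  if (floored) warning("fitted means floored at 1e-12 inside the IRLS weight matrix")

  eta <- drop(X %*% beta)
  mu <- exp(eta)
  w <- pmax(mu, 1e-12)
  z_star <- eta + (y - mu) / w
  names(beta) <- data$column_names
  structure(
    list(beta_hat = beta, mu_hat = mu, weights = w, z_star = z_star,
         converged = converged, n_iter = it, deviance = dev_old),
    class = "poisson_mle"
  )
}

#' @export
print.poisson_mle <- function(x, ...) {
  cat("Poisson MLE (IRLS):", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations; deviance =", format(x$deviance), "\n")
  print(x$beta_hat)
  invisible(x)
}

#' Adjusted (working) response of the Poisson GLM
#'
#' z*_i = log(mu_i) + (y_i - mu_i)/mu_i evaluated at the fitted means.
#'
#' @param fit a \code{poisson_mle} object.
#' @param y observed counts.
#' @return numeric vector of adjusted responses.
#' @export
adjusted_response <- function(fit, y) {
  mu <- fit$mu_hat
  if (any(mu <= 0)) stop("all fitted means must be positive")
  if (length(y) != length(mu)) stop("length(y) must match the fit")
  log(mu) + (y - mu) / mu
}

#' Canonical (eigen) decomposition of the weighted cross-product matrix
#'
#' Computes the spectral decomposition X'WX = Q Lambda Q' of the Fisher
#' information at the MLE, with eigenvalues in descending order. All ridge
#' shrinkage and MSE formulas in this package act componentwise in these
#' canonical coordinates: the rotated design is Z = XQ, the canonical
#' coefficients are alpha = Q' beta_hat, and the canonical MLE is
#' gamma = Lambda^{-1} Z' W z* (identical to alpha at the IRLS fixed point).
#'
#' Eigenvector sign convention: the largest-magnitude entry of each column of
#' Q is made positive, so reported canonical coefficients are reproducible
#' (selectors only use alpha^2 and are unaffected).
#'
#' @param data a \code{\link{count_dataset}}.
#' @param fit the corresponding \code{poisson_mle}.
#' @return An object of class \code{canonical_form}: list with \code{lambdas}
#'   (descending, all > 0), \code{Q}, \code{Z}, \code{alpha},
#'   \code{gamma_mle}, \code{p}, \code{q}, \code{has_intercept}.
#' @export
canonical_decompose <- function(data, fit) {
  stopifnot(inherits(data, "count_dataset"), inherits(fit, "poisson_mle"))
  X <- data$X
  w <- fit$weights
  A <- crossprod(X * sqrt(w))
  e <- eigen(A, symmetric = TRUE)
  lambdas <- e$values
  if (min(lambdas) <= 0) {
    stop("X'WX is not positive definite: smallest eigenvalue = ", format(min(lambdas)))
  }
  Q <- e$vectors
  # fix signs: largest-|.| entry of each eigenvector positive
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Z <- X %*% Q
  alpha <- drop(crossprod(Q, fit$beta_hat))
  gamma_mle <- drop(crossprod(Z, w * fit$z_star) / lambdas)
  structure(
    list(lambdas = lambdas, Q = Q, Z = Z, alpha = alpha, gamma_mle = gamma_mle,
         p = data$p, q = data$q, has_intercept = data$has_intercept,
         column_names = data$column_names),
    class = "canonical_form"
  )
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("Canonical form: p =", x$p, "\n")
  cat("Eigenvalues:", paste(signif(x$lambdas, 6), collapse = ", "), "\n")
  cat("Condition number:", format(signif(condition_number(x), 6)), "\n")
  invisible(x)
}

#' Scalar mean squared error of the maximum likelihood estimator
#'
#' trace of (X'WX)^{-1}, i.e. the sum of reciprocal eigenvalues. This is the
#' quantity inflated by multicollinearity: near-dependent columns make the
#' smallest eigenvalues tiny and their reciprocals dominate.
#'
#' @param cf a \code{canonical_form}.
#' @return sum over j of 1/lambda_j.
#' @export
mle_scalar_mse <- function(cf) {
  lam <- if (inherits(cf, "canonical_form")) cf$lambdas else cf
  if (any(lam <= 0)) stop("eigenvalues must be positive")
  sum(1 / lam)
}

#' Condition number of the weighted cross-product matrix
#'
#' Ratio of the largest to the smallest eigenvalue of X'WX. Values above
#' roughly 1000 are conventionally read as severe multicollinearity.
#'
#' @param cf a \code{canonical_form}.
#' @return lambda_max / lambda_min (>= 1).
#' @export
condition_number <- function(cf) {
  lam <- if (inherits(cf, "canonical_form")) cf$lambdas else cf
  if (min(lam) <= 0) stop("eigenvalues must be positive")
  max(lam) / min(lam)
}
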