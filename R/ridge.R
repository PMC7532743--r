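ESTIMATORS <- c("MLE", "PRRE", "AUPRRE", "MAUPRRE")

#' Componentwise shrinkage factors of the ridge-type estimators
#'
#' Each estimator multiplies the j-th canonical MLE coordinate by a factor
#' in (0, 1]:
#' \itemize{
#'   \item MLE: 1
#'   \item PRRE (ordinary Poisson ridge): lambda/(lambda + k)
#'   \item AUPRRE (almost unbiased ridge): 1 - k^2/(lambda + k)^2
#'   \item MAUPRRE (modified almost unbiased): the AUPRRE factor times an
#'     additional ridge factor, (1 - k^2/(lambda + k)^2)(1 - k/(lambda + k))
#' }
#' All factors are 1 at k = 0, so every estimator collapses to the MLE there.
#'
#' @param lambdas positive eigenvalues.
#' @param k ridge parameter, k >= 0.
#' @param estimator one of "MLE", "PRRE", "AUPRRE", "MAUPRRE".
#' @return vector of shrinkage factors, one per eigenvalue.
#' @export
shrinkage_factors <- function(lambdas, k, estimator) {
  estimator <- match.arg(estimator, ESTIMATORS)
  if (!(is.numeric(k) && length(k) == 1 && k >= 0)) stop("`k` must be a scalar >= 0")
  switch(estimator,
         MLE = rep(1, length(lambdas)),
         PRRE = lambdas / (lambdas + k),
         AUPRRE = 1 - k^2 / (lambdas + k)^2,
         MAUPRRE = (1 - k^2 / (lambdas + k)^2) * (1 - k / (lambdas + k)))
}

new_ridge_fit <- function(cf, k, estimator, selector_name = "") {
  f <- shrinkage_factors(cf$lambdas, k, estimator)
  gamma <- f * cf$alpha
  beta <- drop(cf$Q %*% gamma)
  names(beta) <- cf$column_names
  structure(
    list(estimator = estimator, k = k,
         beta_hat = beta, gamma = gamma,
         se = standard_errors(cf, estimator, k),
         selector_name = selector_name),
    class = "ridge_fit"
  )
}

#' Poisson ridge regression estimator (PRRE)
#'
#' Shrinks the canonical MLE coordinates by lambda_j/(lambda_j + k);
#' equivalently (X'WX + kI)^{-1} X'WX beta_MLE on the original scale.
#'
#' @param cf a \code{canonical_form}.
#' @param fit the \code{poisson_mle} the canonical form came from (kept for
#'   interface symmetry; the canonical form already carries gamma).
#' @param k ridge parameter >= 0.
#' @param selector_name optional label of the rule that chose k.
#' @return a \code{ridge_fit}.
#' @export
prre <- function(cf, fit = NULL, k, selector_name = "") {
  new_ridge_fit(cf, k, "PRRE", selector_name)
}

#' Almost unbiased Poisson ridge regression estimator (AUPRRE)
#'
#' Applies the one-step bias correction of the ridge estimator: the
#' canonical coordinates are multiplied by 1 - k^2/(lambda_j + k)^2,
#' equivalently [I + k(X'WX + kI)^{-1}][I - k(X'WX + kI)^{-1}] beta_MLE.
#' Compared with PRRE it trades a little variance for a much smaller bias.
#'
#' @inheritParams prre
#' @return a \code{ridge_fit}.
#' @export
auprre <- function(cf, fit = NULL, k, selector_name = "") {
  new_ridge_fit(cf, k, "AUPRRE", selector_name)
}

#' Modified almost unbiased Poisson ridge regression estimator (MAUPRRE)
#'
#' Composes the AUPRRE with an extra ridge-style factor:
#' gamma_j is multiplied by (1 - k^2/(lambda_j + k)^2)(1 - k/(lambda_j + k)).
#'
#' @inheritParams prre
#' @return a \code{ridge_fit}.
#' @export
mauprre <- function(cf, fit = NULL, k, selector_name = "") {
  new_ridge_fit(cf, k, "MAUPRRE", selector_name)
}

#' Standard errors of the ridge-type estimators
#'
#' Square roots of the diagonal of Q C Q', where C is the estimator's
#' canonical covariance matrix conditional on the converged weights:
#' diag(f_j^2 / lambda_j) with f_j the estimator's shrinkage factor
#' (f = 1 for the MLE, giving Lambda^{-1}).
#'
#' @param cf a \code{canonical_form}.
#' @param estimator one of "MLE", "PRRE", "AUPRRE", "MAUPRRE".
#' @param k ridge parameter (ignored for MLE).
#' @return vector of standard errors on the original coefficient scale.
#' @export
standard_errors <- function(cf, estimator, k = 0) {
  estimator <- match.arg(estimator, ESTIMATORS)
  f <- shrinkage_factors(cf$lambdas, k, estimator)
  cdiag <- f^2 / cf$lambdas
  sqrt(drop((cf$Q^2) %*% cdiag))
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(x$estimator, "fit, k =", format(signif(x$k, 6)),
      if (nzchar(x$selector_name)) paste0("(", x$selector_name, ")") else "", "\n")
  print(data.frame(estimate = x$beta_hat, se = x$se))
  invisible(x)
}
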