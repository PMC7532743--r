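#' Canonical inputs for the closed-form bias/covariance/MSE theory
#'
#' The MSE theory of the ridge-type estimators depends on the data only
#' through the eigenvalues lambda of X'WX, the canonical coefficients alpha,
#' and the ridge parameter k; this container carries exactly those.
#'
#' @param lambdas positive eigenvalues.
#' @param alpha canonical coefficient vector, same length.
#' @param k ridge parameter >= 0.
#' @return an object of class \code{theory_input}.
#' @export
theory_input <- function(lambdas, alpha, k) {
  if (length(lambdas) != length(alpha)) stop("`lambdas` and `alpha` must have the same length")
  if (any(lambdas <= 0)) stop("all eigenvalues must be positive")
  if (!(is.numeric(k) && length(k) == 1 && k >= 0)) stop("`k` must be a scalar >= 0")
  structure(list(lambdas = as.numeric(lambdas), alpha = as.numeric(alpha), k = k),
            class = "theory_input")
}

#' Canonical bias vector of an estimator
#'
#' Bias is defined as E(estimate) - beta, which in canonical coordinates is
#' (f_j - 1) alpha_j with f_j the estimator's shrinkage factor:
#' PRRE gives -k/(lambda+k) alpha, AUPRRE gives -k^2/(lambda+k)^2 alpha, and
#' MAUPRRE gives (s_j - 1) alpha with
#' s_j = (1 - k^2/(lambda+k)^2)(1 - k/(lambda+k)). The MLE is unbiased.
#'
#' @param ti a \code{theory_input}.
#' @param estimator one of "MLE", "PRRE", "AUPRRE", "MAUPRRE".
#' @return bias vector in canonical coordinates.
#' @export
bias_vector <- function(ti, estimator) {
  estimator <- match.arg(estimator, ESTIMATORS)
  f <- shrinkage_factors(ti$lambdas, ti$k, estimator)
  (f - 1) * ti$alpha
}

#' Canonical covariance matrix of an estimator
#'
#' diag(f_j^2 / lambda_j), conditional on the converged IRLS weights:
#' Lambda^{-1} for the MLE, Lambda_k^{-1} Lambda Lambda_k^{-1} for PRRE,
#' (I - k^2 Lambda_k^{-2}) Lambda^{-1} (I - k^2 Lambda_k^{-2}) for AUPRRE,
#' and the MAUPRRE sandwich with the extra ridge factors.
#'
#' @inheritParams bias_vector
#' @return covariance matrix (diagonal) in canonical coordinates.
#' @export
ridge_covariance <- function(ti, estimator) {
  estimator <- match.arg(estimator, ESTIMATORS)
  f <- shrinkage_factors(ti$lambdas, ti$k, estimator)
  diag(f^2 / ti$lambdas, nrow = length(ti$lambdas))
}

#' Matrix mean squared error of an estimator
#'
#' MMSE = Cov + bias bias'.
#'
#' @inheritParams bias_vector
#' @return matrix MSE in canonical coordinates.
#' @export
matrix_mse <- function(ti, estimator) {
  b <- bias_vector(ti, estimator)
  ridge_covariance(ti, estimator) + tcrossprod(b)
}

#' Scalar mean squared error of an estimator
#'
#' trace of the matrix MSE: sum of f_j^2/lambda_j plus the squared bias norm.
#' For MLE, PRRE and AUPRRE this coincides with the usual printed closed
#' forms sum 1/lambda, sum (lambda + k^2 alpha^2)/(lambda+k)^2 and
#' sum (1/lambda)(1 - k^2/(lambda+k)^2)^2 + sum k^4 alpha^2/(lambda+k)^4.
#'
#' For MAUPRRE the authoritative value is the trace-based one,
#' trace(Cov) + ||bias||^2. A widely circulated closed-form summation for the
#' MAUPRRE scalar MSE is internally inconsistent with that trace (its
#' variance term squares an extra ridge ratio and its bias term does not
#' square the bracket); setting \code{as_printed = TRUE} evaluates that
#' literal summation for comparison purposes only.
#'
#' @inheritParams bias_vector
#' @param as_printed for MAUPRRE only: evaluate the literal (inconsistent)
#'   closed-form summation instead of the trace (default FALSE).
#' @return scalar MSE.
#' @export
scalar_mse <- function(ti, estimator, as_printed = FALSE) {
  estimator <- match.arg(estimator, ESTIMATORS)
  lam <- ti$lambdas; a <- ti$alpha; k <- ti$k
  if (estimator == "MAUPRRE" && as_printed) {
    r <- k^2 / (lam + k)^2
    return(sum((1 / lam) * (1 - r)^2 * (lam / (lam + k)^2)^2) +
           sum((k^2 * a^2 / (lam + k)^2) *
               (1 + k / (lam + k)^2 - k^2 / (lam + k)^2)))
  }
  f <- shrinkage_factors(lam, k, estimator)
  b <- (f - 1) * a
  sum(f^2 / lam) + sum(b^2)
}

#' Full closed-form MSE report for one estimator at one k
#'
#' @inheritParams bias_vector
#' @return list with estimator, k, bias_vector, covariance, matrix_mse and
#'   scalar_mse (all in canonical coordinates).
#' @export
mse_report <- function(ti, estimator) {
  estimator <- match.arg(estimator, ESTIMATORS)
  list(estimator = estimator, k = ti$k,
       bias_vector = bias_vector(ti, estimator),
       covariance = ridge_covariance(ti, estimator),
       matrix_mse = matrix_mse(ti, estimator),
       scalar_mse = scalar_mse(ti, estimator))
}

#' Scalar MSE difference between two estimators
#'
#' scalar_mse(first) - scalar_mse(second); positive means the second
#' estimator dominates at this (lambda, alpha, k).
#'
#' @param ti a \code{theory_input}.
#' @param first,second distinct estimator names.
#' @return the signed difference.
#' @export
mse_difference <- function(ti, first, second) {
  first <- match.arg(first, ESTIMATORS)
  second <- match.arg(second, ESTIMATORS)
  if (first == second) stop("`first` and `second` must name different estimators")
  scalar_mse(ti, first) - scalar_mse(ti, second)
}

#' Per-component dominance thresholds in k
#'
#' For each canonical component, the lower bound on k above which the AUPRRE
#' beats the PRRE in scalar MSE,
#' k* = (3 - lambda alpha^2 + sqrt((3 + lambda alpha^2)^2 +
#' 4 lambda alpha^2)) / (4 alpha^2), and the upper bound below which the
#' AUPRRE beats the MLE, (2 lambda + lambda sqrt(2(1 + lambda alpha^2))) /
#' (lambda alpha^2 - 1), the latter applying only when lambda alpha^2 > 1
#' (otherwise the AUPRRE beats the MLE for every k > 0 and the bound is
#' reported as Inf). Components with alpha_j = 0 get an infinite lower bound.
#'
#' @param lambdas positive eigenvalues.
#' @param alpha canonical coefficients.
#' @return data.frame with columns component, lambda, alpha, lambda_alpha2,
#'   k_lower_auprre_vs_prre, k_upper_auprre_vs_mle.
#' @export
theorem_thresholds <- function(lambdas, alpha) {
  if (length(lambdas) != length(alpha)) stop("lengths differ")
  if (any(lambdas <= 0)) stop("all eigenvalues must be positive")
  la2 <- lambdas * alpha^2
  lower <- ifelse(alpha == 0, Inf,
                  (3 - la2 + sqrt((3 + la2)^2 + 4 * la2)) / (4 * alpha^2))
  upper <- ifelse(la2 > 1,
                  (2 * lambdas + lambdas * sqrt(2 * (1 + la2))) / (la2 - 1),
                  Inf)
  data.frame(component = seq_along(lambdas), lambda = lambdas, alpha = alpha,
             lambda_alpha2 = la2,
             k_lower_auprre_vs_prre = lower,
             k_upper_auprre_vs_mle = upper)
}

#' Quadratic-form dominance condition for the MAUPRRE
#'
#' Numeric checker for the matrix-MSE dominance of the MAUPRRE over a
#' baseline estimator: with b the MAUPRRE bias and D = Cov(baseline) -
#' Cov(MAUPRRE) (positive definite for k > 0), the MMSE difference
#' MMSE(baseline) - MMSE(MAUPRRE) is nonnegative definite when
#' b' D^{-1} b <= 1 (Farebrother-type condition). The check is numeric
#' (eigenvalue sign test), not symbolic.
#'
#' @param ti a \code{theory_input} with k > 0.
#' @param baseline one of "MLE", "PRRE", "AUPRRE".
#' @return list with the quadratic form value, whether the condition holds,
#'   and the minimum eigenvalue of the MMSE difference matrix.
#' @export
mauprre_dominance_condition <- function(ti, baseline = c("MLE", "PRRE", "AUPRRE")) {
  baseline <- match.arg(baseline)
  b <- bias_vector(ti, "MAUPRRE")
  d <- diag(ridge_covariance(ti, baseline)) - diag(ridge_covariance(ti, "MAUPRRE"))
  qform <- if (all(d > 0)) sum(b^2 / d) else NA_real_
  diff_mat <- matrix_mse(ti, baseline) - matrix_mse(ti, "MAUPRRE")
  min_eig <- min(eigen(diff_mat, symmetric = TRUE, only.values = TRUE)$values)
  list(baseline = baseline,
       quadratic_form = qform,
       condition_holds = is.finite(qform) && qform <= 1,
       min_eigen_mmse_difference = min_eig)
}

#' Squared bias and scalar MSE of all four estimators over a grid of k
#'
#' Produces a long-format table suitable for plotting MSE-versus-k curves.
#'
#' @param lambdas positive eigenvalues.
#' @param alpha canonical coefficients.
#' @param k_grid nonnegative, nondecreasing vector of ridge values.
#' @return data.frame with columns k, estimator, squared_bias, scalar_mse.
#' @export
mse_curve <- function(lambdas, alpha, k_grid) {
  if (length(k_grid) == 0) stop("`k_grid` must be nonempty")
  if (any(k_grid < 0)) stop("`k_grid` must be nonnegative")
  if (is.unsorted(k_grid)) stop("`k_grid` must be sorted increasing")
  rows <- lapply(k_grid, function(k) {
    ti <- theory_input(lambdas, alpha, k)
    data.frame(k = k, estimator = ESTIMATORS,
               squared_bias = vapply(ESTIMATORS, function(e) sum(bias_vector(ti, e)^2), 0),
               scalar_mse = vapply(ESTIMATORS, function(e) scalar_mse(ti, e), 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
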