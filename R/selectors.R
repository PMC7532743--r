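SELECTORS <- c("k_TO", "k_q1", "k_q2", "k_q3", "k_q4")

#' Residual-based dispersion estimate used by the ridge selectors
#'
#' sigma2 = sum((y - mu)^2) / (n - q + 1), where q counts the non-intercept
#' regressors. Note the denominator is n - q + 1, not the usual residual
#' degrees of freedom n - q - 1; this matches the selector literature this
#' package implements and is kept as printed.
#'
#' @param y observed counts.
#' @param mu_hat fitted means.
#' @param q number of non-intercept regressors.
#' @return the scalar dispersion estimate.
#' @export
sigma2_hat <- function(y, mu_hat, q) {
  n <- length(y)
  if (length(mu_hat) != n) stop("length(mu_hat) must equal length(y)")
  denom <- n - q + 1
  if (denom <= 0) stop("nonpositive denominator n - q + 1")
  sum((y - mu_hat)^2) / denom
}

#' Componentwise optimal ridge parameter for the AUPRRE
#'
#' The value k_j = (1 + sqrt(1 + alpha_j^2 lambda_j)) / alpha_j^2 that zeroes
#' the derivative of the j-th component of the AUPRRE scalar MSE,
#' (1/lambda)(1 - k^2/(lambda+k)^2)^2 + k^4 alpha^2/(lambda+k)^4, in k.
#'
#' @param cf a \code{canonical_form}, or a list with elements \code{lambdas}
#'   and \code{alpha}.
#' @return vector of per-component optimal ridge values.
#' @export
optimal_k_components <- function(cf) {
  lam <- cf$lambdas
  alpha <- cf$alpha
  if (any(alpha == 0)) stop("optimal k undefined: some canonical coefficient alpha_j is zero")
  (1 + sqrt(1 + alpha^2 * lam)) / alpha^2
}

new_k_selection <- function(name, value, components, s2) {
  if (!is.finite(value) || value <= 0) stop("selector '", name, "' produced a nonpositive value")
  structure(list(name = name, value = value, components = components, sigma2_hat = s2),
            class = "k_selection")
}

#' Median-based ridge selector
#'
#' k = median over components of sigma2 / alpha_j^2. For an even number of
#' components the median is the mean of the two central order statistics.
#'
#' @param cf a \code{canonical_form}.
#' @param s2 dispersion estimate from \code{\link{sigma2_hat}}.
#' @return a \code{k_selection}.
#' @export
k_TO <- function(cf, s2) {
  alpha <- cf$alpha
  if (any(alpha == 0)) stop("k_TO undefined: some canonical coefficient alpha_j is zero")
  if (!(is.numeric(s2) && length(s2) == 1 && s2 > 0)) stop("`s2` must be a positive scalar")
  comps <- s2 / alpha^2
  new_k_selection("k_TO", stats::median(comps), comps, s2)
}

#' Optimal-value-based ridge selectors k_q1 to k_q4
#'
#' Per-component candidates c_j = (sigma2 + sqrt(sigma2 + alpha_j^2
#' lambda_j)) / alpha_j^2 (which reduce to the componentwise AUPRRE-optimal
#' values when sigma2 = 1), aggregated into a single ridge parameter:
#' arithmetic mean (k_q1), median (k_q2), maximum (k_q3) or geometric mean
#' (k_q4). The geometric mean is taken over all p components the design
#' actually has, intercept included when present.
#'
#' @param cf a \code{canonical_form}.
#' @param s2 dispersion estimate, > 0.
#' @param aggregator one of "mean", "median", "max", "geometric_mean".
#' @return a \code{k_selection} named k_q1..k_q4 according to the aggregator.
#' @export
k_q <- function(cf, s2, aggregator = c("mean", "median", "max", "geometric_mean")) {
  aggregator <- match.arg(aggregator)
  alpha <- cf$alpha
  lam <- cf$lambdas
  if (any(alpha == 0)) stop("k_q undefined: some canonical coefficient alpha_j is zero")
  if (!(is.numeric(s2) && length(s2) == 1 && s2 > 0)) stop("`s2` must be a positive scalar")
  comps <- (s2 + sqrt(s2 + alpha^2 * lam)) / alpha^2
  value <- switch(aggregator,
                  mean = mean(comps),
                  median = stats::median(comps),
                  max = max(comps),
                  geometric_mean = exp(mean(log(comps))))
  name <- switch(aggregator, mean = "k_q1", median = "k_q2",
                 max = "k_q3", geometric_mean = "k_q4")
  new_k_selection(name, value, comps, s2)
}

#' Evaluate a set of ridge selectors on a fitted model
#'
#' @param cf a \code{canonical_form}.
#' @param fit the \code{poisson_mle}.
#' @param y observed counts.
#' @param selectors subset of c("k_TO","k_q1","k_q2","k_q3","k_q4").
#' @return named list of \code{k_selection} objects.
#' @export
select_k <- function(cf, fit, y, selectors = SELECTORS) {
  selectors <- match.arg(selectors, SELECTORS, several.ok = TRUE)
  s2 <- sigma2_hat(y, fit$mu_hat, cf$q)
  out <- lapply(selectors, function(s) {
    switch(s,
           k_TO = k_TO(cf, s2),
           k_q1 = k_q(cf, s2, "mean"),
           k_q2 = k_q(cf, s2, "median"),
           k_q3 = k_q(cf, s2, "max"),
           k_q4 = k_q(cf, s2, "geometric_mean"))
  })
  names(out) <- selectors
  out
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Ridge selector", x$name, ": k =", format(signif(x$value, 6)), "\n")
  cat("components:", paste(signif(x$components, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Write a selector report to CSV
#'
#' One row per selector with its value, plus per-component candidates.
#'
#' @param selections named list of \code{k_selection} objects.
#' @param path output file path.
#' @return the report data frame, invisibly.
#' @export
write_selector_report <- function(selections, path) {
  rows <- lapply(selections, function(s) {
    data.frame(name = s$name, value = s$value,
               component = seq_along(s$components),
               component_value = s$components,
               sigma2_hat = s$sigma2_hat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
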