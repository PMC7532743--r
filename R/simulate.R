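#' Define one Monte Carlo design cell
#'
#' One cell of the factorial experiment comparing the estimators under
#' controlled collinearity: regressors with pairwise population correlation
#' rho^2, Poisson responses with log link, and true slopes normalized so
#' their squared sum is one.
#'
#' @param rho collinearity driver in [0, 1); pairwise regressor correlation
#'   is rho^2.
#' @param q number of regressors.
#' @param n sample size.
#' @param R number of Monte Carlo replications.
#' @param beta true slope vector (length q); defaults to 1/sqrt(q) for every
#'   slope, the standard normalization sum(beta^2) = 1, which is enforced.
#' @param include_intercept fit (and generate with) an intercept; default
#'   TRUE with value \code{intercept}.
#' @param intercept true intercept value (default 0).
#' @param seed integer seed for the cell's random stream.
#' @param k_selectors subset of c("k_TO","k_q1","k_q2","k_q3","k_q4").
#' @param estimators subset of c("MLE","PRRE","AUPRRE","MAUPRRE").
#' @param redraw_X redraw the design every replicate (default TRUE); FALSE
#'   holds X fixed across replicates for conditional-MSE experiments.
#' @param mse_scope "all" (default) accumulates squared error and absolute
#'   bias over every fitted coefficient, intercept included; "slopes"
#'   restricts to the non-intercept coefficients.
#' @return an object of class \code{simulation_design}.
#' @export
simulation_design <- function(rho, q, n, R,
                              beta = rep(1 / sqrt(q), q),
                              include_intercept = TRUE, intercept = 0,
                              seed = 1L,
                              k_selectors = SELECTORS,
                              estimators = ESTIMATORS,
                              redraw_X = TRUE,
                              mse_scope = c("all", "slopes")) {
  if (!(rho >= 0 && rho < 1)) stop("`rho` must lie in [0, 1)")
  if (R < 1) stop("`R` must be >= 1")
  if (length(beta) != q) stop("`beta` must have length q")
  if (abs(sum(beta^2) - 1) > 1e-12) stop("slope vector must satisfy sum(beta^2) = 1")
  k_selectors <- match.arg(k_selectors, SELECTORS, several.ok = TRUE)
  estimators <- match.arg(estimators, ESTIMATORS, several.ok = TRUE)
  structure(
    list(rho = rho, q = q, n = n, R = as.integer(R), beta = beta,
         include_intercept = include_intercept, intercept = intercept,
         seed = as.integer(seed), k_selectors = k_selectors,
         estimators = estimators, redraw_X = redraw_X,
         mse_scope = match.arg(mse_scope)),
    class = "simulation_design"
  )
}

#' Generate collinear standard-normal regressors
#'
#' x_ij = sqrt(1 - rho^2) z_ij + rho z_{i,q+1} with z independent standard
#' normal draws, so each column has population variance 1 and every pair of
#' columns has population correlation rho^2.
#'
#' @param n sample size.
#' @param q number of columns.
#' @param rho collinearity driver in [0, 1).
#' @param seed optional integer seed (set only when supplied, so callers
#'   managing their own stream can omit it).
#' @return n x q matrix with columns x1..xq.
#' @export
generate_regressors <- function(n, q, rho, seed = NULL) {
  if (!(rho >= 0 && rho < 1)) stop("`rho` must lie in [0, 1)")
  if (n < 1 || q < 1) stop("`n` and `q` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * (q + 1)), n, q + 1)
  X <- sqrt(1 - rho^2) * z[, seq_len(q), drop = FALSE] + rho * z[, q + 1]
  colnames(X) <- paste0("x", seq_len(q))
  X
}

#' Draw Poisson responses from a log-linear mean
#'
#' y_i ~ Poisson(mu_i) independently, mu_i = exp(intercept + x_i' beta).
#'
#' @param X design matrix (regressors only, no intercept column).
#' @param beta slope vector.
#' @param intercept intercept value (default 0).
#' @param seed optional integer seed.
#' @return integer count vector of length nrow(X).
#' @export
generate_response <- function(X, beta, intercept = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- exp(intercept + drop(X %*% beta))
  if (any(!is.finite(mu))) stop("non-finite Poisson means: linear predictor too large")
  stats::rpois(length(mu), mu)
}

# one (estimator, selector) combination label table for a design
cell_combos <- function(design) {
  est <- setdiff(design$estimators, "MLE")
  combos <- data.frame(estimator = character(0), selector = character(0),
                       stringsAsFactors = FALSE)
  if ("MLE" %in% design$estimators) {
    combos <- rbind(combos, data.frame(estimator = "MLE", selector = "none"))
  }
  for (s in design$k_selectors) {
    for (e in est) combos <- rbind(combos, data.frame(estimator = e, selector = s))
  }
  combos
}

#' Run one Monte Carlo design cell
#'
#' For each replicate: generate the regressors (redrawn each replicate by
#' default), draw Poisson counts, fit the MLE by IRLS, form the canonical
#' decomposition, evaluate every requested ridge selector, and compute every
#' requested estimator at each selected k. Accumulates, per (estimator,
#' selector), the empirical MSE (1/R) sum (betahat - beta)'(betahat - beta)
#' and absolute bias (1/R) sum over components |betahat_j - beta_j|.
#' Replicates whose IRLS fit fails to converge (or whose canonical
#' coefficients degenerate) are redrawn, capped at 10 attempts each, and
#' counted in \code{n_failed}.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param k_override force this ridge value for every estimator and selector
#'   (mainly k_override = 0 for collapse checks); default NULL uses the
#'   data-driven selectors.
#' @return data.frame with one row per (estimator, selector): columns rho, q,
#'   n, R, selector, estimator, mc_mse, mc_abs_bias, mc_se_of_mse, n_failed.
#' @export
run_cell <- function(design, k_override = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  combos <- cell_combos(design)
  m <- nrow(combos)
  R <- design$R
  q <- design$q
  beta_true <- if (design$include_intercept) c(design$intercept, design$beta) else design$beta
  keep <- if (design$mse_scope == "slopes" && design$include_intercept) {
    seq_along(beta_true)[-1]
  } else {
    seq_along(beta_true)
  }

  sq_err <- matrix(NA_real_, R, m)
  abs_err <- matrix(NA_real_, R, m)
  n_failed <- 0L
  X <- NULL

  for (r in seq_len(R)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      if (attempt > 10L) stop("replicate ", r, " failed to produce a convergent fit in 10 attempts")
      if (is.null(X) || design$redraw_X || attempt > 1L) {
        X <- generate_regressors(design$n, q, design$rho)
      }
      y <- generate_response(X, design$beta, design$intercept)
      Xfit <- if (design$include_intercept) cbind(`(Intercept)` = 1, X) else X
      res <- tryCatch(suppressWarnings({
        ds <- count_dataset(y, Xfit)
        fit <- fit_poisson_mle(ds)
        if (!fit$converged) stop("IRLS did not converge")
        cf <- canonical_decompose(ds, fit)
        if (any(cf$alpha == 0)) stop("degenerate canonical coefficients")
        list(fit = fit, cf = cf)
      }), error = function(e) NULL)
      if (!is.null(res)) break
      n_failed <- n_failed + 1L
    }
    fit <- res$fit
    cf <- res$cf
    ks <- if (is.null(k_override)) {
      vapply(select_k(cf, fit, y, design$k_selectors), function(s) s$value, 0)
    } else {
      stats::setNames(rep(k_override, length(design$k_selectors)), design$k_selectors)
    }
    for (i in seq_len(m)) {
      est <- combos$estimator[i]
      k <- if (est == "MLE") 0 else unname(ks[combos$selector[i]])
      f <- shrinkage_factors(cf$lambdas, k, est)
      bhat <- drop(cf$Q %*% (f * cf$alpha))
      err <- (bhat - beta_true)[keep]
      sq_err[r, i] <- sum(err^2)
      abs_err[r, i] <- sum(abs(err))
    }
  }

  data.frame(rho = design$rho, q = q, n = design$n, R = R,
             selector = combos$selector, estimator = combos$estimator,
             mc_mse = colMeans(sq_err),
             mc_abs_bias = colMeans(abs_err),
             mc_se_of_mse = apply(sq_err, 2, stats::sd) / sqrt(R),
             n_failed = n_failed,
             stringsAsFactors = FALSE)
}

#' Build a factorial grid of design cells
#'
#' Crosses the supplied factor levels and assigns each cell a seed derived
#' from the master seed by a fixed counter scheme (master + 104729 * cell
#' index, modulo 2^31 - 1), so cells are reproducible and order-insensitive.
#'
#' @param rho,q,n vectors of factor levels.
#' @param R replications per cell.
#' @param master_seed integer master seed.
#' @param ... passed on to \code{\link{simulation_design}}.
#' @return list of \code{simulation_design} objects.
#' @export
design_grid <- function(rho, q, n, R, master_seed = 1L, ...) {
  cells <- expand.grid(rho = rho, q = q, n = n, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    simulation_design(rho = cells$rho[i], q = cells$q[i], n = cells$n[i], R = R,
                      seed = as.integer((master_seed + 104729 * (i - 1)) %% 2147483647L),
                      ...)
  })
}

#' Run a list of design cells
#'
#' @param designs nonempty list of \code{simulation_design} objects.
#' @return row-bound \code{\link{run_cell}} results over all cells.
#' @export
run_grid <- function(designs) {
  if (length(designs) == 0) stop("`designs` must be a nonempty list")
  keyify <- function(d) paste(d$rho, d$q, d$n, d$R, d$seed, sep = "|")
  keys <- vapply(designs, keyify, "")
  if (anyDuplicated(keys)) warning("duplicate design cells in the grid")
  do.call(rbind, lapply(designs, run_cell))
}

#' Pivot tidy simulation results into a wide estimator-by-selector layout
#'
#' One row per (rho, q, n, estimator) with a column per selector, mirroring
#' the usual presentation of simulation MSE tables.
#'
#' @param results output of \code{\link{run_cell}} / \code{\link{run_grid}}.
#' @param value which column to spread, "mc_mse" (default) or "mc_abs_bias".
#' @return wide-format data.frame.
#' @export
widen_results <- function(results, value = c("mc_mse", "mc_abs_bias")) {
  value <- match.arg(value)
  results$cell <- interaction(results$rho, results$q, results$n, results$estimator, drop = TRUE)
  wide <- stats::reshape(
    results[c("rho", "q", "n", "estimator", "selector", value)],
    idvar = c("rho", "q", "n", "estimator"),
    timevar = "selector", direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  rownames(wide) <- NULL
  wide
}
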