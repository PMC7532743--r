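#' Construct a count dataset for Poisson regression
#'
#' Bundles a vector of nonnegative integer counts with a numeric design
#' matrix. The design may carry an explicit leading intercept column of ones;
#' whether it does is recorded so that downstream ridge-parameter selectors
#' can distinguish the number of substantive regressors from the total number
#' of fitted coefficients.
#'
#' @param y vector of nonnegative integer counts, length n.
#' @param X numeric matrix, n rows. Must have full column rank and n > ncol(X).
#' @param column_names optional character vector of column names for X.
#'
#' @return An object of class \code{count_dataset}: a list with elements
#'   \code{y}, \code{X}, \code{column_names}, \code{n}, \code{p},
#'   \code{has_intercept} (TRUE when the first column is constant one) and
#'   \code{q} (number of non-intercept regressors).
#' @export
count_dataset <- function(y, X, column_names = NULL) {
  y <- as.vector(y)
  if (!is.numeric(y)) stop("`y` must be numeric counts")
  if (anyNA(y)) stop("`y` contains missing values")
  if (any(y < 0)) stop("`y` must be nonnegative counts")
  if (any(abs(y - round(y)) > 1e-8)) stop("`y` must be integer-valued counts")
  y <- round(y)

  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("`X` contains missing or non-finite values")
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= p) stop("need more observations than columns (n > p)")
  if (qr(X)$rank < p) stop("singular design: `X` is rank-deficient")

  if (is.null(column_names)) column_names <- colnames(X)
  if (is.null(column_names)) column_names <- paste0("x", seq_len(p))
  if (length(column_names) != p) stop("`column_names` must have one entry per column of X")
  colnames(X) <- column_names

  has_intercept <- all(abs(X[, 1] - 1) < 1e-12)
  structure(
    list(y = y, X = X, column_names = column_names,
         n = n, p = p,
         has_intercept = has_intercept,
         q = p - as.integer(has_intercept)),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("Count dataset: n =", x$n, ", p =", x$p,
      if (x$has_intercept) "(with intercept column)" else "", "\n")
  cat("Regressors:", paste(x$column_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a count dataset from a CSV file
#'
#' Expects a header row, one response column of nonnegative integer counts,
#' and numeric regressor columns. Cells must be complete (NA rejected);
#' decimal point is '.' regardless of locale.
#'
#' @param path path to a CSV file.
#' @param response name of the response column.
#' @param intercept prepend a column of ones (default TRUE).
#' @param standardize center and scale the regressor columns before adding
#'   the intercept (default FALSE; the eigen-analysis is otherwise performed
#'   on the raw design).
#' @return a \code{\link{count_dataset}}.
#' @export
read_count_csv <- function(path, response, intercept = TRUE, standardize = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!response %in% names(df)) stop("response column '", response, "' not found")
  if (anyNA(df)) stop("NA cells are not allowed in input data")
  y <- df[[response]]
  Xdf <- df[names(df) != response]
  if (!all(vapply(Xdf, is.numeric, logical(1)))) stop("all regressor columns must be numeric")
  X <- as.matrix(Xdf)
  if (standardize) X <- scale(X)
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  count_dataset(y, X)
}

#' Write a coefficient/standard-error summary to CSV
#'
#' Long-format table with columns term, estimator, k, selector, estimate, se.
#'
#' @param fits list of \code{ridge_fit} objects (MLE included as a
#'   \code{ridge_fit} with k = 0).
#' @param path output file path.
#' @return the summary data frame, invisibly.
#' @export
write_fit_summary <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    data.frame(term = names(f$beta_hat),
               estimator = f$estimator,
               k = f$k,
               selector = f$selector_name,
               estimate = unname(f$beta_hat),
               se = unname(f$se),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
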