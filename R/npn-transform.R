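#' Truncation level for the Winsorized empirical CDF
#'
#' Returns the truncation parameter \eqn{\delta_n = 1 / (4 n^{1/4}
#' \sqrt{\pi \log n})} used to clamp the empirical CDF away from 0 and 1
#' before the normal-quantile transform. The rate balances the bias
#' introduced by truncation against the variance of the empirical CDF in
#' the tails; it decreases slowly in \eqn{n}, so even large samples keep a
#' small protective band.
#'
#' @param n Sample size (a single integer, at least 2).
#' @return A number in \eqn{(0, 1/2)}.
#' @examples
#' npn_delta_n(100)
#' @export
npn_delta_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2) {
    stop("`n` must be a single number >= 2", call. = FALSE)
  }
  1 / (4 * n^0.25 * sqrt(pi * log(n)))
}

#' Winsorized empirical CDF of a single variable
#'
#' Evaluates the empirical CDF \eqn{\hat F(t) = n^{-1} \#\{x \le t\}} at
#' each observation and clamps the result to \eqn{[\delta_n, 1 -
#' \delta_n]}. Ties share the same value (the count includes every equal
#' observation), so the output is a non-decreasing function of the input
#' ranks.
#'
#' @param x Numeric vector of observations (no missing values).
#' @param delta_n Truncation level in \eqn{(0, 1/2)}; see [npn_delta_n()].
#' @return Numeric vector of truncated probabilities, same length as `x`.
#' @examples
#' npn_winsorized_cdf(c(1, 2, 3, 4), delta_n = 0.3)
#' @export
npn_winsorized_cdf <- function(x, delta_n) {
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  check_scalar_prob(delta_n, "delta_n")
  if (delta_n >= 0.5) stop("`delta_n` must be < 1/2", call. = FALSE)
  f_hat <- rank(x, ties.method = "max") / length(x)
  pmin(pmax(f_hat, delta_n), 1 - delta_n)
}

#' Impute latent Gaussian data through the Winsorized transform
#'
#' Estimates the unknown monotone marginal transformations of a
#' nonparanormal sample and imputes the latent Gaussian variables. For
#' each column \eqn{j} the Winsorized empirical CDF \eqn{\tilde F_j} is
#' mapped through the standard-normal quantile function, giving scores
#' \eqn{z_{mj} = \Phi^{-1}(\tilde F_j(y_{mj}))}; the imputed value is
#' \eqn{x^*_{mj} = \hat\mu_j + \hat\sigma_j z_{mj}}, where \eqn{\hat\mu_j}
#' and \eqn{\hat\sigma_j} are the mean and the 1/n-normalised standard
#' deviation of the raw observed column. The standardized scores depend on
#' the data only through ranks, so they are exactly invariant under
#' strictly increasing marginal transformations.
#'
#' @param data Samples-by-variables numeric matrix or data frame with at
#'   least 4 samples, 2 variables, no missing entries and no constant
#'   column.
#' @param delta_n Optional truncation level override; defaults to
#'   [npn_delta_n()] evaluated at the sample size.
#' @param standardize Location/scale convention for the imputed values:
#'   `"raw"` (default) rescales the quantile scores by the observed-column
#'   mean and scale as in the original estimator; `"latent"` returns the
#'   mean-0/scale-1 scores themselves.
#' @return An object of class `npn_imputed` with elements `values` (the
#'   imputed matrix), `scores` (the standardized quantile scores),
#'   `mu_hat`, `sigma_hat`, `delta_n`, `covariance` (the 1/n sample
#'   covariance of the imputed values), `n` and `p`.
#' @examples
#' y <- matrix(rexp(80), 20, 4)
#' imp <- npn_impute(y)
#' imp$delta_n
#' @export
npn_impute <- function(data, delta_n = NULL,
                       standardize = c("raw", "latent")) {
  standardize <- match.arg(standardize)
  x <- as_input_matrix(data)
  validate_observed(x)
  n <- nrow(x)
  p <- ncol(x)
  dn <- delta_n %||% npn_delta_n(n)
  check_scalar_prob(dn, "delta_n")
  if (dn >= 0.5) stop("`delta_n` must be < 1/2", call. = FALSE)

  mu_hat <- colMeans(x)
  sigma_hat <- sqrt(colMeans(sweep(x, 2L, mu_hat, "-")^2))
  if (any(sigma_hat <= 0)) {
    stop("constant column: zero scale estimate", call. = FALSE)
  }

  scores <- apply(x, 2L, function(col) qnorm(npn_winsorized_cdf(col, dn)))
  dimnames(scores) <- dimnames(x)

  values <- if (standardize == "raw") {
    sweep(sweep(scores, 2L, sigma_hat, "*"), 2L, mu_hat, "+")
  } else {
    scores
  }

  structure(
    list(values = values, scores = scores, mu_hat = mu_hat,
         sigma_hat = sigma_hat, delta_n = dn, covariance = cov1(values),
         n = n, p = p, standardize = standardize,
         variable_ids = colnames(x), sample_ids = rownames(x)),
    class = "npn_imputed"
  )
}

#' @export
print.npn_imputed <- function(x, ...) {
  cat(sprintf(
    "Winsorized latent-Gaussian imputation: %d samples x %d variables\n",
    x$n, x$p))
  cat(sprintf("  delta_n = %.5f, standardize = %s\n", x$delta_n,
              x$standardize))
  invisible(x)
}

#' Sample covariance of imputed latent data
#'
#' The 1/n-normalised centred cross-product matrix \eqn{\tilde\Sigma =
#' n^{-1} \sum_m (x^*_m - \bar x^*)(x^*_m - \bar x^*)^T} of the imputed
#' values, a consistent surrogate for the covariance of the unobserved
#' latent Gaussian data.
#'
#' @param x An `npn_imputed` object or a numeric matrix
#'   (samples-by-variables, at least 2 samples).
#' @return A symmetric positive semi-definite matrix.
#' @export
npn_covariance <- function(x) {
  m <- if (inherits(x, "npn_imputed")) x$values else as_input_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  cov1(m)
}
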