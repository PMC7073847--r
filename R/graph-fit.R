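#' Correlation-scale gram matrix for node-wise regression
#'
#' Builds the p-by-p matrix the node-wise regressions operate on. With
#' `source = "imputed"` it is the Pearson correlation of the imputed (or
#' supplied) columns. With `source = "adjusted_spearman"` it is the
#' rank-based estimator \eqn{2 \sin(\pi \rho_S / 6)} applied entrywise to
#' the Spearman correlation matrix, which is consistent for the latent
#' Gaussian correlation under any strictly monotone marginals; its
#' diagonal is forced to 1. The adjusted-Spearman matrix is not guaranteed
#' positive semi-definite, which downstream solvers tolerate.
#'
#' @param x An `npn_imputed` object or a samples-by-variables numeric
#'   matrix (at least 4 samples).
#' @param source `"adjusted_spearman"` (default) or `"imputed"`.
#' @return A symmetric p-by-p matrix with unit diagonal.
#' @export
gram_matrix <- function(x, source = c("adjusted_spearman", "imputed")) {
  source <- match.arg(source)
  m <- if (inherits(x, "npn_imputed")) x$values else as_input_matrix(x)
  validate_observed(m, min_n = 4L)
  g <- if (source == "imputed") {
    cor(m)
  } else {
    rs <- cor(m, method = "spearman")
    a <- 2 * sin(pi * rs / 6)
    diag(a) <- 1
    a
  }
  if (any(!is.finite(g))) {
    stop("gram matrix has non-finite entries (constant column?)",
         call. = FALSE)
  }
  g
}

check_node_index <- function(j, p) {
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j > p || j != round(j)) {
    stop("`j` must be a single column index", call. = FALSE)
  }
  as.integer(j)
}

#' Gram-form lasso for one node-wise regression
#'
#' Minimises \eqn{\frac12 \beta^T G_{-j,-j} \beta - G_{-j,j}^T \beta +
#' \lambda \lVert\beta\rVert_1} by cyclic coordinate descent with
#' soft-thresholding, declaring convergence when the largest coefficient
#' change in a sweep falls below `tol`.
#'
#' @param gram Symmetric p-by-p matrix with positive diagonal.
#' @param j Target node (column index).
#' @param lambda Non-negative penalty.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Sweep cap; non-convergence yields a warning and the
#'   best iterate.
#' @return Named coefficient vector of length p-1 (the other variables).
#' @export
nodewise_lasso <- function(gram, j, lambda, tol = 1e-7, max_iter = 10000L) {
  check_symmetric(gram)
  p <- nrow(gram)
  j <- check_node_index(j, p)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  }
  fit <- cd_lasso_path_cpp(gram[-j, -j, drop = FALSE], gram[-j, j],
                           lambda, tol, as.integer(max_iter))
  if (!fit$converged[1L]) {
    warning(sprintf("coordinate descent did not converge for node %d; %s",
                    j, "returning best iterate"), call. = FALSE)
  }
  setNames(fit$beta[, 1L], colnames(gram)[-j])
}

#' Gram-form Dantzig selector for one node-wise regression
#'
#' Solves \eqn{\min \lVert\beta\rVert_1} subject to
#' \eqn{\lVert G_{-j,-j}\beta - G_{-j,j}\rVert_\infty \le \lambda} as a
#' linear program in the positive/negative parts of \eqn{\beta}.
#'
#' @inheritParams nodewise_lasso
#' @return Named coefficient vector of length p-1.
#' @export
nodewise_dantzig <- function(gram, j, lambda) {
  check_symmetric(gram)
  p <- nrow(gram)
  j <- check_node_index(j, p)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  }
  gs <- gram[-j, -j, drop = FALSE]
  g <- gram[-j, j]
  m <- p - 1L
  if (lambda <= 1e-12) {
    # the feasible set degenerates to the least-squares point
    return(setNames(drop(solve(gs, g)), colnames(gram)[-j]))
  }
  amat <- rbind(cbind(gs, -gs), cbind(-gs, gs))
  bvec <- c(lambda + g, lambda - g)
  sol <- tryCatch(
    pracma::linprog(rep(1, 2L * m), A = amat, b = bvec,
                    maxiter = 200L * m),
    error = function(e) {
      stop(sprintf("Dantzig LP failed for node %d: %s", j,
                   conditionMessage(e)), call. = FALSE)
    })
  beta <- sol$x[seq_len(m)] - sol$x[m + seq_len(m)]
  # the feasible set is non-empty for every lambda >= 0 (the least-squares
  # solution is feasible at lambda = 0), so a violated constraint means a
  # solver failure
  if (is.null(sol$x) || max(abs(gs %*% beta - g)) > lambda + 1e-6) {
    stop(sprintf("Dantzig LP did not solve for node %d", j),
         call. = FALSE)
  }
  setNames(beta, colnames(gram)[-j])
}

#' Penalty selection by AIC along a 20-point path
#'
#' Builds a log-spaced grid of `n_lambdas` penalties from
#' \eqn{\lambda_{\max} = \max_i |G_{i,j}|} (the smallest penalty with an
#' all-zero solution) down to \eqn{\max(\lambda_{\max}/100,
#' \sqrt{\log p / n}/2)}: the lower endpoint is clamped at half the
#' universal penalty scale \eqn{\sqrt{\log p / n}} because the bias
#' correction of the downstream statistic assumes penalties of that
#' order, and letting the candidate set descend far below it overfits the
#' node-wise regressions and inflates the tails of the test statistics.
#' The chosen solver is fitted at each value (warm starts along the lasso
#' path) and the penalty minimising \eqn{AIC = n \log(RSS/n) + 2\,df} is
#' returned, where the residual sum of squares is computed on the
#' standardized imputed data and \eqn{df} is the number of non-zero
#' coefficients. Ties go to the larger penalty.
#'
#' @param x An `npn_imputed` object or numeric matrix providing the data
#'   on which residuals are evaluated.
#' @param j Target node.
#' @param method `"lasso"` or `"dantzig"`.
#' @param gram Optional precomputed gram matrix; defaults to
#'   [gram_matrix()] of `x` with `gram_source`.
#' @param gram_source Gram construction when `gram` is missing.
#' @param n_lambdas Grid size (at least 2).
#' @return List with `lambda` (selected penalty), `beta` (its coefficient
#'   vector), `grid`, `aic` and `df` along the grid.
#' @export
select_lambda_aic <- function(x, j, method = c("lasso", "dantzig"),
                              gram = NULL,
                              gram_source = c("adjusted_spearman", "imputed"),
                              n_lambdas = 20L) {
  method <- match.arg(method)
  gram_source <- match.arg(gram_source)
  if (!is.numeric(n_lambdas) || length(n_lambdas) != 1L || n_lambdas < 2) {
    stop("`n_lambdas` must be at least 2", call. = FALSE)
  }
  n_lambdas <- as.integer(n_lambdas)
  xs <- if (inherits(x, "npn_imputed")) standardize_cols(x$scores)
        else standardize_cols(as_input_matrix(x))
  if (is.null(gram)) gram <- gram_matrix(x, gram_source)
  check_symmetric(gram)
  p <- ncol(gram)
  j <- check_node_index(j, p)
  n <- nrow(xs)

  lam_max <- max(abs(gram[-j, j]))
  if (lam_max < 1e-12) {
    return(list(lambda = 0, beta = setNames(rep(0, p - 1L),
                                            colnames(gram)[-j]),
                grid = rep(0, n_lambdas), aic = rep(NA_real_, n_lambdas),
                df = rep(0L, n_lambdas)))
  }
  lam_min <- min(lam_max, max(lam_max / 100, 0.5 * sqrt(log(p) / n)))
  grid <- exp(seq(log(lam_max), log(lam_min), length.out = n_lambdas))

  betas <- if (method == "lasso") {
    cd_lasso_path_cpp(gram[-j, -j, drop = FALSE], gram[-j, j],
                      grid, 1e-7, 10000L)$beta
  } else {
    vapply(grid, function(l) nodewise_dantzig(gram, j, l),
           numeric(p - 1L))
  }

  yj <- xs[, j]
  xm <- xs[, -j, drop = FALSE]
  rss <- apply(betas, 2L, function(b) {
    alpha <- mean(yj) - sum(colMeans(xm) * b)
    sum((yj - alpha - drop(xm %*% b))^2)
  })
  df <- colSums(abs(betas) > 1e-10)
  aic <- n * log(rss / n) + 2 * df
  best <- which.min(aic)  # grid is decreasing, so ties pick the larger lambda
  list(lambda = grid[best],
       beta = setNames(betas[, best], colnames(gram)[-j]),
       grid = grid, aic = aic, df = df)
}

#' Residuals and cross-products for a node-wise coefficient matrix
#'
#' Given per-node coefficients \eqn{\hat B} (row j holds the regression of
#' variable j on the others, zero diagonal), computes the fitted
#' intercepts \eqn{\hat\alpha_j = \bar x_j - \bar x_{-j}^T \hat\beta_j},
#' the residual matrix, the uncentred residual cross-products
#' \eqn{r^*_{ij} = n^{-1} \sum_m \epsilon^*_{mi}\epsilon^*_{mj}} and their
#' centred counterpart. For `npn_imputed` input the residuals are
#' evaluated on the standardized quantile scores, matching the
#' correlation-scale gram matrix the coefficients were fitted against.
#'
#' @param x An `npn_imputed` object or numeric samples-by-variables
#'   matrix.
#' @param coefficients p-by-p coefficient matrix with zero diagonal.
#' @return An object of class `nodewise_fit` with elements
#'   `coefficients`, `intercepts`, `residuals`, `cross_products`,
#'   `sigma_eps`, `n`, `p`.
#' @export
residual_stats <- function(x, coefficients) {
  xs <- if (inherits(x, "npn_imputed")) standardize_cols(x$scores)
        else as_input_matrix(x)
  p <- ncol(xs)
  if (!is.matrix(coefficients) || nrow(coefficients) != p ||
      ncol(coefficients) != p) {
    stop("`coefficients` must be a p-by-p matrix matching the data",
         call. = FALSE)
  }
  if (any(abs(diag(coefficients)) > 1e-12)) {
    stop("`coefficients` must have a zero diagonal", call. = FALSE)
  }
  n <- nrow(xs)
  mu <- colMeans(xs)
  intercepts <- vapply(seq_len(p), function(j) {
    mu[j] - sum(mu[-j] * coefficients[j, -j])
  }, numeric(1))
  residuals <- vapply(seq_len(p), function(j) {
    xs[, j] - intercepts[j] - xs[, -j, drop = FALSE] %*% coefficients[j, -j]
  }, numeric(n))
  dimnames(residuals) <- dimnames(xs)
  cross_products <- crossprod(residuals) / n
  structure(
    list(coefficients = coefficients, intercepts = intercepts,
         residuals = residuals, cross_products = cross_products,
         sigma_eps = cov1(residuals), n = n, p = p,
         lambda_used = NULL, method = NULL, gram_source = NULL,
         variable_ids = colnames(xs)),
    class = "nodewise_fit"
  )
}

#' Fit all node-wise regressions for one class
#'
#' Runs the full per-class stage: gram construction, per-node penalty
#' selection by AIC (or a fixed penalty), and residual statistics on the
#' standardized imputed data.
#'
#' @inheritParams select_lambda_aic
#' @param lambda Optional fixed penalty applied to every node, bypassing
#'   AIC selection.
#' @return A `nodewise_fit` (see [residual_stats()]) with `lambda_used`
#'   (per-node penalties), `method` and `gram_source` filled in.
#' @export
fit_nodewise <- function(x, method = c("lasso", "dantzig"),
                         gram_source = c("adjusted_spearman", "imputed"),
                         lambda = NULL, n_lambdas = 20L) {
  method <- match.arg(method)
  gram_source <- match.arg(gram_source)
  gram <- gram_matrix(x, gram_source)
  p <- ncol(gram)
  B <- matrix(0, p, p, dimnames = list(colnames(gram), colnames(gram)))
  lambdas <- numeric(p)
  for (j in seq_len(p)) {
    if (is.null(lambda)) {
      sel <- select_lambda_aic(x, j, method = method, gram = gram,
                               n_lambdas = n_lambdas)
      B[j, -j] <- sel$beta
      lambdas[j] <- sel$lambda
    } else {
      B[j, -j] <- if (method == "lasso") nodewise_lasso(gram, j, lambda)
                  else nodewise_dantzig(gram, j, lambda)
      lambdas[j] <- lambda
    }
  }
  fit <- residual_stats(x, B)
  fit$lambda_used <- lambdas
  fit$method <- method
  fit$gram_source <- gram_source
  fit
}

#' @export
print.nodewise_fit <- function(x, ...) {
  cat(sprintf("Node-wise fit: %d variables, %d samples\n", x$p, x$n))
  if (!is.null(x$method)) {
    cat(sprintf("  method = %s, gram = %s, median lambda = %.4f\n",
                x$method, x$gram_source, median(x$lambda_used)))
  }
  invisible(x)
}

#' Bias-corrected partial-correlation statistics for one class
#'
#' Augments the residual cross-products with the coefficient-weighted
#' residual variances that cancel the first-order shrinkage bias of the
#' node-wise fits: \eqn{N_{ij} = r^*_{ij} + r^*_{ii}\hat B_{j,i} +
#' r^*_{jj}\hat B_{i,j}} (with \eqn{\hat B_{j,i}} the coefficient of
#' variable i in the regression of variable j). Two scalings are kept:
#' `s_star` \eqn{= N_{ij}/(r^*_{ii} r^*_{jj})}, on the precision-entry
#' scale, and `rho_corrected` \eqn{= N_{ij}/\sqrt{r^*_{ii} r^*_{jj}}},
#' which consistently estimates the partial correlation
#' \eqn{\rho_{ij\cdot} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}} and
#' drives the downstream two-sample test. Partial-correlation entries are
#' clipped to \eqn{|\rho| \le 1 - 10^{-10}} and the hard-thresholded
#' matrix \eqn{\hat\rho_{ij} I\{|\hat\rho_{ij}| \ge 2\sqrt{\log p / n}\}}
#' is attached for the variance plug-in.
#'
#' @param fit A `nodewise_fit`.
#' @return An object of class `class_graph_stats` with matrices `s_star`,
#'   `rho_corrected`, `rho_thresholded` (diagonals 1, `s_star` diagonal
#'   `NA`) and scalars `n`, `p`.
#' @export
bias_corrected_stat <- function(fit) {
  if (!inherits(fit, "nodewise_fit")) {
    stop("`fit` must be a `nodewise_fit`", call. = FALSE)
  }
  r <- fit$cross_products
  rii <- diag(r)
  if (any(rii <= 0)) stop("zero residual variance", call. = FALSE)
  B <- fit$coefficients
  corr <- sweep(t(B), 1L, rii, "*")  # corr[i, j] = r_ii * B[j, i]
  N <- r + corr + t(corr)
  denom <- sqrt(outer(rii, rii))
  s_star <- N / outer(rii, rii)
  diag(s_star) <- NA_real_
  rho <- N / denom
  rho <- pmin(pmax(rho, -(1 - 1e-10)), 1 - 1e-10)
  diag(rho) <- 1
  out <- structure(
    list(s_star = s_star, rho_corrected = rho, rho_thresholded = NULL,
         n = fit$n, p = fit$p, variable_ids = fit$variable_ids),
    class = "class_graph_stats"
  )
  out$rho_thresholded <- threshold_partial_corr(out)
  out
}

#' Hard-threshold a partial-correlation matrix
#'
#' Keeps an entry when its magnitude reaches the universal cutoff
#' \eqn{2\sqrt{\log p / n}} and zeroes it otherwise; the diagonal is set
#' to 1. Used as the plug-in for the variance term of the two-sample
#' statistic.
#'
#' @param stats A `class_graph_stats` object, or a numeric matrix (then
#'   `n` must be supplied).
#' @param n Sample size when `stats` is a plain matrix.
#' @return A p-by-p matrix.
#' @export
threshold_partial_corr <- function(stats, n = NULL) {
  if (inherits(stats, "class_graph_stats")) {
    rho <- stats$rho_corrected
    n <- stats$n
  } else {
    rho <- stats
    check_symmetric(rho, "stats")
    if (is.null(n)) stop("`n` required for matrix input", call. = FALSE)
  }
  p <- ncol(rho)
  cutoff <- 2 * sqrt(log(p) / n)
  out <- rho * (abs(rho) >= cutoff)
  diag(out) <- 1
  out
}

#' @export
print.class_graph_stats <- function(x, ...) {
  off <- x$rho_corrected[upper.tri(x$rho_corrected)]
  cat(sprintf(
    "Class graph statistics: p = %d, n = %d; |rho| range %.3f-%.3f\n",
    x$p, x$n, min(abs(off)), max(abs(off))))
  invisible(x)
}
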