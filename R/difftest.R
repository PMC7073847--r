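#' Two-sample differential statistic between two classes
#'
#' Standardised entrywise difference of the bias-corrected
#' partial-correlation estimates of two classes,
#' \deqn{S^{(k,k')}_{ij} = \frac{S^{(k)}_{ij} - S^{(k')}_{ij}}
#'   {\sqrt{(1-\hat\rho_{ij}^{(k)2})^2/n_k +
#'          (1-\hat\rho_{ij}^{(k')2})^2/n_{k'}}},}
#' where the numerator uses the unthresholded estimates and the variance
#' plug-in uses the hard-thresholded ones. The result is symmetric in
#' (i, j), changes sign under a class swap, and has zero diagonal.
#'
#' @param stats_k,stats_k2 `class_graph_stats` objects sharing the same
#'   variable set.
#' @return A p-by-p matrix.
#' @export
two_sample_stat <- function(stats_k, stats_k2) {
  if (!inherits(stats_k, "class_graph_stats") ||
      !inherits(stats_k2, "class_graph_stats")) {
    stop("inputs must be `class_graph_stats` objects", call. = FALSE)
  }
  if (stats_k$p != stats_k2$p) {
    stop("classes have different numbers of variables", call. = FALSE)
  }
  num <- stats_k$rho_corrected - stats_k2$rho_corrected
  v1 <- (1 - stats_k$rho_thresholded^2)^2 / stats_k$n
  v2 <- (1 - stats_k2$rho_thresholded^2)^2 / stats_k2$n
  s <- num / sqrt(v1 + v2)
  diag(s) <- 0
  s
}

#' Sum-squared multi-class statistic
#'
#' Entrywise sum of squares of the pairwise two-sample statistics over all
#' K(K-1)/2 class pairs; non-negative, and for K = 2 simply the square of
#' the single pairwise statistic.
#'
#' @param pairwise List of p-by-p matrices from [two_sample_stat()].
#' @return A non-negative p-by-p matrix.
#' @export
multiclass_stat <- function(pairwise) {
  if (!is.list(pairwise) || length(pairwise) < 1L) {
    stop("`pairwise` must be a non-empty list of matrices", call. = FALSE)
  }
  Reduce(`+`, lapply(pairwise, function(m) m^2))
}

# Imhof-type numerical inversion for P(sum_i w_i Z_i^2 <= x).
imhof_cdf <- function(x, weights) {
  surv_integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(weights, u))) - 0.5 * x * u
    rho <- exp(0.25 * colSums(log1p(outer(weights^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * sum(weights) - 0.5 * x  # limit as u -> 0
    out
  }
  val <- integrate(surv_integrand, 0, Inf, rel.tol = 1e-10,
                   abs.tol = 1e-12, subdivisions = 2000L,
                   stop.on.error = FALSE)$value
  min(max(0.5 - val / pi, 0), 1)
}

#' CDF of a weighted sum of squared standard normals
#'
#' Evaluates \eqn{P(\sum_{i=1}^M \lambda_i Z_i^2 \le s)} for i.i.d.
#' standard normal \eqn{Z_i} and positive weights. Equal weights reduce
#' exactly to a scaled chi-square CDF (in particular M = 1 with unit
#' weight is the \eqn{\chi^2_1} CDF); unequal weights are evaluated by
#' Imhof-type numerical inversion of the characteristic function.
#'
#' @param s Non-negative quantile(s).
#' @param weights Positive weights of length M.
#' @return Probabilities, same length as `s`.
#' @examples
#' weighted_chisq_cdf(3.841459, 1)  # ~0.95
#' @export
weighted_chisq_cdf <- function(s, weights) {
  if (!is.numeric(weights) || length(weights) < 1L || any(weights <= 0) ||
      any(!is.finite(weights))) {
    stop("`weights` must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0)) {
    stop("`s` must be non-negative and finite", call. = FALSE)
  }
  M <- length(weights)
  if (diff(range(weights)) < 1e-14) {
    return(pchisq(s / weights[1L], df = M))
  }
  vapply(s, imhof_cdf, numeric(1), weights = weights)
}

#' Normal-quantile transform of the combined statistic
#'
#' Maps each combined statistic through the weighted chi-square CDF and
#' the standard-normal quantile function, \eqn{T_{ij} =
#' \Phi^{-1}(P(\sum\lambda_i Z_i^2 \le S_{ij}))}. CDF values are clamped
#' to \eqn{[10^{-15}, 1-10^{-15}]} before inversion so every statistic is
#' finite; under the complete null the \eqn{T_{ij}} are approximately
#' standard normal. The diagonal is set to `NA`.
#'
#' @param combined Non-negative p-by-p matrix from [multiclass_stat()].
#' @param weights Positive weights (default a single unit weight, the
#'   two-class case).
#' @return A p-by-p matrix of normal-scale statistics.
#' @export
t_transform <- function(combined, weights = 1) {
  if (any(combined < 0, na.rm = TRUE)) {
    stop("`combined` must be non-negative", call. = FALSE)
  }
  u <- weighted_chisq_cdf(as.vector(combined), weights)
  t_mat <- matrix(qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15)),
                  nrow(combined), ncol(combined),
                  dimnames = dimnames(combined))
  diag(t_mat) <- NA_real_
  t_mat
}

#' Empirically corrected FDR threshold for the normal-scale statistics
#'
#' Finds the smallest threshold t such that the estimated false discovery
#' proportion among \eqn{\{T_{ij} \ge t\}} is below `alpha0`, using the
#' correction factor
#' \deqn{A(t) = \left(1 + \frac{|A|\,|t|\,\phi(t)}{2(1-\Phi(t))}\right)^{-1},
#'   \quad A = \frac{P_0 - \hat P_0}{Q_0},}
#' with \eqn{P_0 = 2\Phi(1)-1}, \eqn{Q_0 = 2\phi(1)} and \eqn{\hat P_0}
#' the observed fraction of \eqn{|T_{ij}| \le 1} among the p(p-1)/2 upper
#' -triangle statistics. The deviation of \eqn{\hat P_0} from its null
#' value \eqn{P_0} measures departure from null calibration and tightens
#' the threshold accordingly. The search scans the observed statistics in
#' \eqn{[0, \sqrt{4\log \tilde p}]} (with \eqn{\tilde p = p(p-1)/2}); if
#' no candidate satisfies the bound the threshold falls back to
#' \eqn{\sqrt{4\log \tilde p}}, rejecting only extreme statistics.
#'
#' @param t_stats p-by-p matrix of normal-scale statistics (diagonal
#'   ignored).
#' @param alpha0 Nominal FDR level in (0, 1).
#' @return List with `threshold`, `rejected` (two-column integer matrix of
#'   upper-triangle index pairs with \eqn{T_{ij} \ge} threshold),
#'   `constants` (`P0`, `P0_hat`, `Q0`, `A`), `fallback` flag, `alpha0`
#'   and `n_tests`.
#' @export
fdr_threshold <- function(t_stats, alpha0) {
  check_scalar_prob(alpha0, "alpha0")
  if (!is.matrix(t_stats) || nrow(t_stats) != ncol(t_stats) ||
      nrow(t_stats) < 2L) {
    stop("`t_stats` must be a square matrix with p >= 2", call. = FALSE)
  }
  p <- nrow(t_stats)
  ut <- t_stats[upper.tri(t_stats)]
  if (any(!is.finite(ut))) {
    stop("`t_stats` has non-finite off-diagonal entries", call. = FALSE)
  }
  p_tilde <- p * (p - 1) / 2

  P0 <- 2 * pnorm(1) - 1
  P0_hat <- mean(abs(ut) <= 1)
  Q0 <- 2 * dnorm(1)
  A <- (P0 - P0_hat) / Q0
  A_fun <- function(t) {
    1 / (1 + abs(A) * abs(t) * dnorm(t) / (2 * (1 - pnorm(t))))
  }

  t_max <- sqrt(4 * log(p_tilde))
  cand <- sort(unique(ut[ut >= 0 & ut <= t_max]))
  threshold <- NA_real_
  for (t in cand) {
    n_reject <- sum(ut >= t)
    if ((1 - pnorm(t)) <= alpha0 * A_fun(t) * max(1, n_reject) / p_tilde) {
      threshold <- t
      break
    }
  }
  fallback <- is.na(threshold)
  if (fallback) threshold <- t_max

  rej <- which(t_stats >= threshold & upper.tri(t_stats), arr.ind = TRUE)
  colnames(rej) <- c("i", "j")
  rej <- rej[order(rej[, 1L], rej[, 2L]), , drop = FALSE]

  list(threshold = threshold, rejected = rej,
       constants = list(P0 = P0, P0_hat = P0_hat, Q0 = Q0, A = A),
       fallback = fallback, alpha0 = alpha0, n_tests = p_tilde)
}

# Wrap a latent Gaussian matrix so the pipeline can skip Winsorized
# imputation (the oracle-data arm of the simulations).
as_latent_imputed <- function(data) {
  x <- as_input_matrix(data)
  validate_observed(x)
  scores <- standardize_cols(x)
  structure(
    list(values = x, scores = scores, mu_hat = colMeans(x),
         sigma_hat = sqrt(colMeans(sweep(x, 2L, colMeans(x), "-")^2)),
         delta_n = NA_real_, covariance = cov1(x),
         n = nrow(x), p = ncol(x), standardize = "oracle",
         variable_ids = colnames(x), sample_ids = rownames(x)),
    class = "npn_imputed"
  )
}

#' Test for differential edges between classes
#'
#' End-to-end differential-network test: Winsorized imputation per class,
#' node-wise regression with AIC-tuned penalties, bias-corrected
#' partial-correlation statistics, pairwise standardised differences,
#' their sum-squared combination mapped to the normal scale, and the
#' empirically corrected FDR threshold. The edge (i, j) is called
#' differential when its normal-scale statistic reaches the threshold.
#'
#' @param data Either a list of per-class samples-by-variables matrices
#'   (or data frames) sharing one variable set, or a single data frame
#'   combined across classes (then `class` must be given).
#' @param class When `data` is a single data frame: the class label of
#'   each row, either as a vector of length `nrow(data)` or the name of
#'   the column of `data` holding the labels.
#' @param alpha0 Nominal FDR level in (0, 1).
#' @param method Node-wise solver, `"lasso"` or `"dantzig"`.
#' @param gram_source `"adjusted_spearman"` (rank-based, default) or
#'   `"imputed"` (Pearson on imputed values).
#' @param n_lambdas AIC grid size per node.
#' @param lambda Optional fixed penalty bypassing AIC selection.
#' @param delta_n Optional truncation-level override passed to
#'   [npn_impute()].
#' @param weights Optional positive weights for the reference weighted
#'   chi-square law with K > 2 classes; defaults to unit weights on all
#'   K(K-1)/2 pairs. For K = 2 the reference law is the single-term
#'   chi-square with one degree of freedom.
#' @param impute If `FALSE`, treat the inputs as already-latent Gaussian
#'   data and skip the Winsorized transform (oracle arm).
#' @return An object of class `dnet_result`; see [tidy.dnet_result()] for
#'   the edge-level table and [glance.dnet_result()] for the run summary.
#' @examples
#' model <- band_precision(p = 12, n_flips = 3, seed = 7)
#' y1 <- sample_nonparanormal(model, n = 60, class_index = 1, seed = 1)
#' y2 <- sample_nonparanormal(model, n = 60, class_index = 2, seed = 2)
#' res <- dnet_test(list(A = y1$observed, B = y2$observed), alpha0 = 0.2)
#' glance(res)
#' @export
dnet_test <- function(data, class = NULL, alpha0 = 0.05,
                      method = c("lasso", "dantzig"),
                      gram_source = c("adjusted_spearman", "imputed"),
                      n_lambdas = 20L, lambda = NULL, delta_n = NULL,
                      weights = NULL, impute = TRUE) {
  method <- match.arg(method)
  gram_source <- match.arg(gram_source)
  check_scalar_prob(alpha0, "alpha0")

  classes <- split_classes(data, class)
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  vids <- colnames(as_input_matrix(classes[[1L]]))
  for (m in classes) {
    if (!identical(colnames(as_input_matrix(m)), vids)) {
      stop("all classes must share the same variable set", call. = FALSE)
    }
  }

  imputed <- lapply(classes, function(m) {
    if (impute) npn_impute(m, delta_n = delta_n) else as_latent_imputed(m)
  })
  fits <- lapply(imputed, fit_nodewise, method = method,
                 gram_source = gram_source, lambda = lambda,
                 n_lambdas = n_lambdas)
  class_stats <- lapply(fits, bias_corrected_stat)

  pairs <- utils::combn(K, 2L, simplify = FALSE)
  pairwise <- lapply(pairs, function(kk) {
    two_sample_stat(class_stats[[kk[1L]]], class_stats[[kk[2L]]])
  })
  names(pairwise) <- vapply(pairs, function(kk) {
    paste(names(classes)[kk], collapse = ":")
  }, character(1))

  M <- length(pairwise)
  w <- weights %||% rep(1, M)
  if (length(w) != M || any(w <= 0)) {
    stop(sprintf("`weights` must be %d positive numbers", M),
         call. = FALSE)
  }

  combined <- multiclass_stat(pairwise)
  t_stats <- t_transform(combined, w)
  fdr <- fdr_threshold(t_stats, alpha0)

  structure(
    list(class_stats = class_stats, fits = fits, pairwise = pairwise,
         combined = combined, t_stats = t_stats,
         threshold = fdr$threshold, rejected = fdr$rejected,
         constants = fdr$constants, fallback = fdr$fallback,
         alpha0 = alpha0, weights = w,
         class_labels = names(classes),
         n_per_class = vapply(imputed, function(i) i$n, integer(1)),
         delta_n = vapply(imputed, function(i) i$delta_n, numeric(1)),
         variable_ids = vids,
         config = list(method = method, gram_source = gram_source,
                       n_lambdas = n_lambdas, lambda = lambda,
                       impute = impute, alpha0 = alpha0)),
    class = "dnet_result"
  )
}

# Normalise the two accepted input shapes into a named list of matrices.
split_classes <- function(data, class) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data))) {
      names(data) <- paste0("class", seq_along(data))
    }
    return(data)
  }
  if (is.null(class)) {
    stop("`class` is required when `data` is a single table", call. = FALSE)
  }
  df <- as.data.frame(data)
  if (is.character(class) && length(class) == 1L && class %in% names(df)) {
    labels <- df[[class]]
    df <- df[setdiff(names(df), class)]
  } else {
    if (length(class) != nrow(df)) {
      stop("`class` must name a column or give one label per row",
           call. = FALSE)
    }
    labels <- class
  }
  lapply(split(df, factor(labels)), as_input_matrix)
}

#' Recompute the FDR threshold of a fitted result at a new level
#'
#' Re-runs only the thresholding stage on the stored normal-scale
#' statistics, so sweeping a grid of FDR levels does not refit the
#' networks.
#'
#' @param result A `dnet_result`.
#' @param alpha0 New nominal FDR level.
#' @return A `dnet_result` with updated threshold and rejection set.
#' @export
dnet_rethreshold <- function(result, alpha0) {
  if (!inherits(result, "dnet_result")) {
    stop("`result` must be a `dnet_result`", call. = FALSE)
  }
  fdr <- fdr_threshold(result$t_stats, alpha0)
  result$threshold <- fdr$threshold
  result$rejected <- fdr$rejected
  result$constants <- fdr$constants
  result$fallback <- fdr$fallback
  result$alpha0 <- alpha0
  result$config$alpha0 <- alpha0
  result
}

#' @export
print.dnet_result <- function(x, ...) {
  cat(sprintf(
    "Differential network test: %d classes (%s), p = %d variables\n",
    length(x$class_labels), paste(x$n_per_class, collapse = "/"),
    length(x$variable_ids)))
  cat(sprintf("  alpha0 = %.3f, threshold = %.4f%s, %d differential edge(s)\n",
              x$alpha0, x$threshold,
              if (x$fallback) " (fallback)" else "", nrow(x$rejected)))
  invisible(x)
}
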