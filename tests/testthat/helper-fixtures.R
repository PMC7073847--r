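# Shared fixtures: all synthetic, generated in code under fixed seeds.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Multivariate Gaussian draw with covariance solve(omega).
rmvn_precision <- function(n, omega, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(omega)
  x <- matrix(rnorm(n * p), n, p) %*% chol(chol2inv(chol(omega)))
  colnames(x) <- paste0("V", seq_len(p))
  x
}

# Random symmetric positive-definite gram matrix with unit diagonal.
random_pd_gram <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  g <- cov2cor(crossprod(a) / p + diag(p) * 0.5)
  dimnames(g) <- list(paste0("V", seq_len(p)), paste0("V", seq_len(p)))
  g
}

# True partial correlation matrix of a precision matrix.
partial_cor <- function(omega) {
  pc <- -omega / sqrt(outer(diag(omega), diag(omega)))
  diag(pc) <- 1
  pc
}

# Gram-form lasso objective.
lasso_objective <- function(gram, j, beta, lambda) {
  gs <- gram[-j, -j, drop = FALSE]
  g <- gram[-j, j]
  0.5 * drop(t(beta) %*% gs %*% beta) - sum(g * beta) +
    lambda * sum(abs(beta))
}

# Brute-force optimum of the Dantzig LP min ||b||_1 s.t.
# ||Gs b - g||_inf <= lam, found by enumerating every basic feasible
# vertex of the positive/negative-part polytope.
dantzig_enum_optimum <- function(gs, g, lam) {
  m <- length(g)
  amat <- rbind(cbind(gs, -gs), cbind(-gs, gs), -diag(2 * m))
  bvec <- c(lam + g, lam - g, rep(0, 2 * m))
  best <- Inf
  for (S in utils::combn(nrow(amat), 2 * m, simplify = FALSE)) {
    M <- amat[S, , drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    x <- tryCatch(solve(M, bvec[S]), error = function(e) NULL)
    if (is.null(x) || any(amat %*% x > bvec + 1e-9)) next
    best <- min(best, sum(x))
  }
  best
}

# Minimal class_graph_stats stand-in for arithmetic tests of the
# two-sample statistic.
fake_class_stats <- function(rho, rho_thresholded, n) {
  structure(
    list(s_star = rho, rho_corrected = rho,
         rho_thresholded = rho_thresholded, n = n, p = ncol(rho),
         variable_ids = colnames(rho)),
    class = "class_graph_stats"
  )
}

# Independent exhaustive-scan oracle for the FDR threshold: evaluates the
# rejection rule at every observed statistic (and the fallback bound)
# without any early exit, returning the least admissible threshold.
fdr_threshold_oracle <- function(t_stats, alpha0) {
  p <- nrow(t_stats)
  ut <- t_stats[upper.tri(t_stats)]
  p_tilde <- p * (p - 1) / 2
  P0 <- 2 * pnorm(1) - 1
  P0_hat <- sum(abs(ut) <= 1) / p_tilde
  A <- (P0 - P0_hat) / (2 * dnorm(1))
  t_max <- sqrt(4 * log(p_tilde))
  cand <- sort(unique(ut[ut >= 0 & ut <= t_max]))
  ok <- vapply(cand, function(t) {
    a_t <- 1 / (1 + abs(A) * abs(t) * dnorm(t) / (2 * (1 - pnorm(t))))
    (1 - pnorm(t)) <= alpha0 * a_t * max(1, sum(ut >= t)) / p_tilde
  }, logical(1))
  if (any(ok)) min(cand[ok]) else t_max
}
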