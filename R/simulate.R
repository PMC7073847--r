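# Synthetic benchmark generators: two precision-matrix designs with
# sign-flipped differential edges, nonparanormal sampling, and the
# eFDR/power scoring protocol.

new_precision_model <- function(omega1, omega2, differential_edges,
                                graph_type, seed, diag_shift) {
  vids <- paste0("V", seq_len(ncol(omega1)))
  dimnames(omega1) <- dimnames(omega2) <- list(vids, vids)
  structure(
    list(omega1 = omega1, omega2 = omega2,
         differential_edges = differential_edges, graph_type = graph_type,
         seed = seed, diag_shift = diag_shift, p = ncol(omega1)),
    class = "precision_model"
  )
}

#' @export
print.precision_model <- function(x, ...) {
  cat(sprintf(
    "%s-graph precision model: p = %d, %d differential edge(s), diag shift %.3f\n",
    x$graph_type, x$p, nrow(x$differential_edges), x$diag_shift))
  invisible(x)
}

#' Band-graph precision model with sign-flipped differential edges
#'
#' Builds the tridiagonal precision matrix with unit diagonal and 0.6 on
#' the first off-diagonals, randomly selects `n_flips` of its p-1 edges
#' and flips their signs (symmetrically) in the second class, then adds
#' \eqn{\max(|\lambda_{\min}(\Omega_1)|, |\lambda_{\min}(\Omega_2)|) +
#' 0.05} to both diagonals so both matrices are positive definite.
#'
#' @param p Number of variables (at least 3).
#' @param n_flips Number of differential edges, between 0 and p-1.
#' @param seed Optional integer seed for the edge selection.
#' @return An object of class `precision_model` with elements `omega1`,
#'   `omega2`, `differential_edges` (two-column index matrix),
#'   `graph_type`, `seed`, `diag_shift`.
#' @export
band_precision <- function(p, n_flips, seed = NULL) {
  if (p < 3L) stop("`p` must be at least 3", call. = FALSE)
  edges <- cbind(i = seq_len(p - 1L), j = 2:p)
  if (n_flips < 0L || n_flips > nrow(edges)) {
    stop(sprintf("`n_flips` must be between 0 and %d", nrow(edges)),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  omega1 <- diag(p)
  for (e in seq_len(p - 1L)) {
    omega1[e, e + 1L] <- omega1[e + 1L, e] <- 0.6
  }
  omega2 <- omega1
  flip <- if (n_flips > 0L) sort(sample.int(p - 1L, n_flips)) else integer(0)
  for (e in flip) {
    omega2[e, e + 1L] <- omega2[e + 1L, e] <- -omega1[e, e + 1L]
  }
  shift <- max(abs(min(eigen(omega1, symmetric = TRUE,
                             only.values = TRUE)$values)),
               abs(min(eigen(omega2, symmetric = TRUE,
                             only.values = TRUE)$values))) + 0.05
  diag(omega1) <- diag(omega1) + shift
  diag(omega2) <- diag(omega2) + shift
  new_precision_model(omega1, omega2, edges[flip, , drop = FALSE],
                      "band", seed, shift)
}

#' Erdős–Rényi precision model with sign-flipped differential edges
#'
#' Connects each node pair independently with probability `connect_prob`,
#' draws each edge weight uniformly from \eqn{[-1/2,-1/4] \cup [1/4,1/2]},
#' shrinks all off-diagonal entries by a factor of 5 (magnitudes end up in
#' [0.05, 0.1]) and sets the diagonal to one. A fraction `flip_frac` of
#' the existing edges (at least one) is sign-flipped in the second class.
#' The construction is diagonally dominant with high probability; if
#' either matrix is not positive definite, \eqn{|\lambda_{\min}| + 0.05}
#' is added to both diagonals.
#'
#' @param p Number of variables (at least 3).
#' @param connect_prob Edge probability in (0, 1).
#' @param flip_frac Fraction of edges flipped in class 2, in (0, 1), or 0
#'   for a null model.
#' @param seed Optional integer seed.
#' @return A `precision_model`; see [band_precision()].
#' @export
er_precision <- function(p, connect_prob = 0.05, flip_frac = 0.05,
                         seed = NULL) {
  if (p < 3L) stop("`p` must be at least 3", call. = FALSE)
  check_scalar_prob(connect_prob, "connect_prob")
  if (flip_frac < 0 || flip_frac >= 1) {
    stop("`flip_frac` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  for (attempt in 1:100) {
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < connect_prob
    if (any(on)) break
    warning("Erdős–Rényi draw produced no edges; redrawing", call. = FALSE)
  }
  if (!any(on)) stop("could not draw a non-empty graph", call. = FALSE)
  edges <- pairs[on, , drop = FALSE]
  colnames(edges) <- c("i", "j")
  w <- runif(nrow(edges), 0.25, 0.5) * sample(c(-1, 1), nrow(edges),
                                              replace = TRUE)
  w <- w / 5
  omega1 <- diag(p)
  omega1[edges] <- w
  omega1[edges[, c(2L, 1L), drop = FALSE]] <- w

  n_flip <- if (flip_frac > 0) max(1L, round(flip_frac * nrow(edges)))
            else 0L
  flip <- if (n_flip > 0L) sort(sample.int(nrow(edges), n_flip))
          else integer(0)
  omega2 <- omega1
  fe <- edges[flip, , drop = FALSE]
  omega2[fe] <- -omega1[fe]
  omega2[fe[, c(2L, 1L), drop = FALSE]] <- -omega1[fe]

  lmin <- min(eigen(omega1, symmetric = TRUE, only.values = TRUE)$values,
              eigen(omega2, symmetric = TRUE, only.values = TRUE)$values)
  shift <- 0
  if (lmin <= 0) {
    shift <- abs(lmin) + 0.05
    diag(omega1) <- diag(omega1) + shift
    diag(omega2) <- diag(omega2) + shift
  }
  new_precision_model(omega1, omega2, fe, "er", seed, shift)
}

# Strictly increasing marginal transforms available to the sampler.
transform_library <- list(
  identity = function(x) x,
  exp = function(x) exp(x),
  cube = function(x) x^3,
  logistic = function(x) stats::plogis(x)
)

#' Draw a nonparanormal sample from a precision model
#'
#' Draws n latent vectors from \eqn{N(0, \Omega^{-1})} for the requested
#' class and applies a strictly increasing transform to each column;
#' `"identity"` reproduces the oracle-data experiment, while `"exp"`,
#' `"cube"` and `"logistic"` exercise the nonparanormal layer without
#' changing column ranks.
#'
#' @param model A `precision_model`.
#' @param n Sample size (at least 4).
#' @param class_index 1 or 2, selecting \eqn{\Omega_1} or \eqn{\Omega_2}.
#' @param transforms Transform name(s) from `"identity"`, `"exp"`,
#'   `"cube"`, `"logistic"`: a single name recycled across variables or a
#'   vector of length p.
#' @param seed Optional integer seed.
#' @return A list of class `npn_sample` with `observed` (transformed),
#'   `latent` (the Gaussian draw) and `transforms`.
#' @export
sample_nonparanormal <- function(model, n, class_index = 1L,
                                 transforms = "identity", seed = NULL) {
  if (!inherits(model, "precision_model")) {
    stop("`model` must be a `precision_model`", call. = FALSE)
  }
  if (n < 4L) stop("`n` must be at least 4", call. = FALSE)
  if (!class_index %in% c(1L, 2L)) {
    stop("`class_index` must be 1 or 2", call. = FALSE)
  }
  omega <- if (class_index == 1L) model$omega1 else model$omega2
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix is not positive definite",
                         call. = FALSE)
  p <- model$p
  transforms <- if (length(transforms) == 1L) rep(transforms, p)
                else transforms
  if (length(transforms) != p ||
      !all(transforms %in% names(transform_library))) {
    stop(sprintf("`transforms` must be from {%s}, length 1 or p",
                 paste(names(transform_library), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- chol2inv(chol(omega))
  latent <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  colnames(latent) <- colnames(omega)
  rownames(latent) <- paste0("S", seq_len(n))
  observed <- latent
  for (j in seq_len(p)) {
    observed[, j] <- transform_library[[transforms[j]]](latent[, j])
  }
  structure(list(observed = observed, latent = latent,
                 transforms = transforms, class_index = class_index),
            class = "npn_sample")
}

edge_key <- function(idx) paste(idx[, 1L], idx[, 2L], sep = "-")

# FDP and TPR of one set of edge calls against the ground truth, with the
# max(R, 1) convention in the denominator of the FDP.
score_edge_calls <- function(called, truth) {
  fp <- sum(!called %in% truth)
  tp <- sum(called %in% truth)
  c(fdp = fp / max(length(called), 1L),
    tpr = if (length(truth) > 0L) tp / length(truth) else NA_real_)
}

#' Score eFDR and power of the test on a simulated design
#'
#' Repeats the full protocol `reps` times: draw both classes from the
#' model, run [dnet_test()] once, re-threshold at every level of
#' `alpha_grid`, and score the false discovery proportion
#' FP / max(R, 1) and the true positive rate TP / #differential-edges
#' against the model's ground truth. Per-level averages over replicates
#' are reported.
#'
#' @param model A `precision_model`.
#' @param n1,n2 Per-class sample sizes.
#' @param alpha_grid Nominal FDR levels, default `seq(0.05, 0.50, 0.05)`.
#' @param reps Number of replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it, so the
#'   whole report is reproducible.
#' @param transforms Marginal transforms passed to
#'   [sample_nonparanormal()].
#' @param oracle If `TRUE`, run the test on the latent Gaussian data
#'   without Winsorized imputation (the oracle arm).
#' @param ... Further arguments to [dnet_test()] (e.g. `method`,
#'   `gram_source`, `n_lambdas`).
#' @return An object of class `dnet_perf` whose `summary` element is a
#'   tibble with columns `alpha`, `efdr`, `power`.
#' @export
evaluate_performance <- function(model, n1 = 100L, n2 = 100L,
                                 alpha_grid = seq(0.05, 0.50, by = 0.05),
                                 reps = 10L, seed = NULL,
                                 transforms = "identity", oracle = FALSE,
                                 ...) {
  if (!inherits(model, "precision_model")) {
    stop("`model` must be a `precision_model`", call. = FALSE)
  }
  if (reps < 1L) stop("`reps` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * reps)
  truth <- edge_key(model$differential_edges)
  n_true <- length(truth)

  fdp <- matrix(NA_real_, reps, length(alpha_grid))
  tpr <- matrix(NA_real_, reps, length(alpha_grid))
  for (r in seq_len(reps)) {
    y1 <- sample_nonparanormal(model, n1, 1L, transforms,
                               seed = rep_seeds[2L * r - 1L])
    y2 <- sample_nonparanormal(model, n2, 2L, transforms,
                               seed = rep_seeds[2L * r])
    d1 <- if (oracle) y1$latent else y1$observed
    d2 <- if (oracle) y2$latent else y2$observed
    res <- dnet_test(list(class1 = d1, class2 = d2),
                     alpha0 = alpha_grid[1L], impute = !oracle, ...)
    for (a in seq_along(alpha_grid)) {
      res_a <- dnet_rethreshold(res, alpha_grid[a])
      sc <- score_edge_calls(edge_key(res_a$rejected), truth)
      fdp[r, a] <- sc["fdp"]
      tpr[r, a] <- sc["tpr"]
    }
  }
  structure(
    list(summary = tibble::tibble(alpha = alpha_grid,
                                  efdr = colMeans(fdp),
                                  power = colMeans(tpr)),
         fdp = fdp, tpr = tpr, reps = reps, model = model,
         n1 = n1, n2 = n2, oracle = oracle, seed = seed,
         transforms = transforms),
    class = "dnet_perf"
  )
}

#' @export
print.dnet_perf <- function(x, ...) {
  cat(sprintf(
    "Simulation performance: %s graph, p = %d, n = %d/%d, %d reps%s\n",
    x$model$graph_type, x$model$p, x$n1, x$n2, x$reps,
    if (x$oracle) " (oracle data)" else ""))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
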