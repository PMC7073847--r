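# Input coercion and validation shared across modules.

# Coerce a samples-by-variables input (matrix or data frame) to a numeric
# matrix, preserving dimnames and inventing them when absent.
as_input_matrix <- function(data, arg = "data") {
  if (is.data.frame(data)) {
    non_num <- !vapply(data, is.numeric, logical(1))
    if (any(non_num)) {
      stop(sprintf("non-numeric column(s) in `%s`: %s", arg,
                   paste(names(data)[non_num], collapse = ", ")),
           call. = FALSE)
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    stop(sprintf("`%s` must be a numeric matrix or data frame", arg),
         call. = FALSE)
  }
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("V", seq_len(ncol(data)))
  }
  if (is.null(rownames(data))) {
    rownames(data) <- paste0("S", seq_len(nrow(data)))
  }
  data
}

# Observed-matrix contract: enough samples, enough variables, finite
# entries, and at least two distinct values per column.
validate_observed <- function(x, min_n = 4L, arg = "data") {
  if (nrow(x) < min_n) {
    stop(sprintf("`%s` needs at least %d samples, got %d", arg, min_n,
                 nrow(x)), call. = FALSE)
  }
  if (ncol(x) < 2L) {
    stop(sprintf("`%s` needs at least 2 variables", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains missing or non-finite entries", arg),
         call. = FALSE)
  }
  n_distinct <- apply(x, 2L, function(col) length(unique(col)))
  if (any(n_distinct < 2L)) {
    stop(sprintf("constant column(s) in `%s`: %s", arg,
                 paste(colnames(x)[n_distinct < 2L], collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Centre columns and scale by the 1/n standard deviation.
standardize_cols <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  s <- sqrt(colMeans(xc^2))
  if (any(s <= 0)) stop("constant column cannot be standardized", call. = FALSE)
  sweep(xc, 2L, s, "/")
}

# 1/n-normalised centred cross-product matrix.
cov1 <- function(x) {
  xc <- sweep(x, 2L, colMeans(x), "-")
  crossprod(xc) / nrow(x)
}

check_symmetric <- function(m, arg = "gram") {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE))) {
    stop(sprintf("`%s` must be a symmetric matrix", arg), call. = FALSE)
  }
  invisible(m)
}

check_scalar_prob <- function(x, arg, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    stop(sprintf("`%s` must be a single number in (0, 1)", arg),
         call. = FALSE)
  }
  invisible(x)
}
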