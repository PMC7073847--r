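#' Median- and variance-matching batch correction
#'
#' Removes batch (or age-group) effects one variable at a time by mapping
#' each within-batch distribution onto the overall location and scale:
#' \deqn{g^*_{ijk} = M_i + (g_{ijk} - M_{ij})\,\hat\sigma_{g_i} /
#'   \hat\sigma_{g_{ij}},}
#' where \eqn{M_i} and \eqn{\hat\sigma_{g_i}} are the median and standard
#' deviation of variable i over all samples and \eqn{M_{ij}},
#' \eqn{\hat\sigma_{g_{ij}}} the same within batch j. A single batch
#' returns the input unchanged.
#'
#' @param data Samples-by-variables numeric matrix or data frame.
#' @param batch Batch label per sample (length `nrow(data)`); any atomic
#'   vector.
#' @param sd_method `"sample"` (1/(n-1), default) or `"population"`
#'   (1/n) normalisation for both standard deviations.
#' @return Corrected data of the same type and dimensions as `data`
#'   (tibble in, tibble out).
#' @examples
#' x <- data.frame(g = c(1, 2, 3, 11, 12, 13))
#' batch_correct(cbind(x, h = rev(x$g)), batch = rep(c("a", "b"), each = 3))
#' @export
batch_correct <- function(data, batch, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  x <- as_input_matrix(data)
  if (length(batch) != nrow(x)) {
    stop("`batch` must give one label per sample", call. = FALSE)
  }
  batch <- factor(batch)
  if (nlevels(batch) == 1L) {
    return(restore_type(x, data))
  }
  if (any(table(batch) < 2L)) {
    stop("every batch needs at least 2 samples", call. = FALSE)
  }
  sdev <- if (sd_method == "sample") stats::sd
          else function(v) sqrt(mean((v - mean(v))^2))
  out <- x
  for (j in seq_len(ncol(x))) {
    g <- x[, j]
    m_i <- median(g)
    s_i <- sdev(g)
    for (b in levels(batch)) {
      idx <- batch == b
      s_ij <- sdev(g[idx])
      if (s_ij <= 0) {
        stop(sprintf("zero within-batch SD for variable `%s` in batch `%s`",
                     colnames(x)[j], b), call. = FALSE)
      }
      out[idx, j] <- m_i + (g[idx] - median(g[idx])) * s_i / s_ij
    }
  }
  restore_type(out, data)
}

restore_type <- function(mat, template) {
  if (tibble::is_tibble(template)) return(tibble::as_tibble(mat))
  if (is.data.frame(template)) return(as.data.frame(mat))
  mat
}

#' Read an expression matrix, optionally split by class
#'
#' Reads a delimited text file (TSV or CSV, chosen by extension) with a
#' header row and sample identifiers in the first column, returning a
#' samples-by-variables matrix. Files stored genes-in-rows are transposed
#' via the `orientation` flag. Samples whose fraction of missing values
#' exceeds `max_missing` are dropped (with a message giving the count);
#' any missing value remaining in a retained sample is an error, since
#' the test does not impute missing entries.
#'
#' @param path Path to the delimited file.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @param metadata Optional sample metadata: a data frame or path to a
#'   delimited file with columns `sample_id` and `class`. When given, the
#'   return value is a named list of per-class matrices.
#' @param max_missing Highest tolerated fraction of missing values per
#'   sample before the sample is dropped (default 0.01).
#' @return A numeric matrix, or a named list of matrices when `metadata`
#'   is supplied.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows",
                                                   "genes_in_rows"),
                                   metadata = NULL, max_missing = 0.01) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- read_delimited(path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    stop(sprintf("non-numeric column(s) in %s: %s", path,
                 paste(names(df[-1L])[bad], collapse = ", ")),
         call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "genes_in_rows") m <- t(m)

  frac_missing <- rowMeans(is.na(m))
  drop <- frac_missing > max_missing
  if (any(drop)) {
    message(sprintf("dropping %d sample(s) with > %.1f%% missing values",
                    sum(drop), 100 * max_missing))
    m <- m[!drop, , drop = FALSE]
  }
  if (anyNA(m)) {
    stop("missing values remain after sample filtering; remove or impute them upstream",
         call. = FALSE)
  }
  if (is.null(metadata)) return(m)

  md <- if (is.character(metadata)) read_delimited(metadata) else
    as.data.frame(metadata)
  if (!all(c("sample_id", "class") %in% names(md))) {
    stop("metadata needs `sample_id` and `class` columns", call. = FALSE)
  }
  unknown <- setdiff(rownames(m), as.character(md$sample_id))
  if (length(unknown) > 0L) {
    stop(sprintf("samples without metadata: %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")),
         call. = FALSE)
  }
  labels <- md$class[match(rownames(m), as.character(md$sample_id))]
  lapply(split(as.data.frame(m), factor(labels)), as.matrix)
}

read_delimited <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    stop(sprintf("parse error in %s at line %d: %s", path,
                 probs$row[1L], probs$expected[1L]), call. = FALSE)
  }
  out
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: writes a samples-by-variables
#' matrix as TSV or CSV (by extension) with sample identifiers in the
#' first column, optionally transposed to genes-in-rows.
#'
#' @param x Samples-by-variables numeric matrix or data frame.
#' @param path Output path (`.tsv` or `.csv`).
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path,
                                    orientation = c("samples_in_rows",
                                                    "genes_in_rows")) {
  orientation <- match.arg(orientation)
  m <- as_input_matrix(x)
  if (orientation == "genes_in_rows") m <- t(m)
  df <- tibble::as_tibble(m, rownames = "sample_id")
  if (orientation == "genes_in_rows") names(df)[1L] <- "gene_id"
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}
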