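# broom-style accessors and ggplot2 methods for the result objects.

#' Tidy the edge-level output of a differential-network test
#'
#' One row per tested variable pair (upper triangle), with the combined
#' sum-squared statistic, its normal-scale transform and the rejection
#' flag.
#'
#' @param x A `dnet_result`.
#' @param ... Unused.
#' @return A tibble with columns `var_i`, `var_j`, `statistic`,
#'   `t_value`, `rejected`, sorted by decreasing `t_value`.
#' @method tidy dnet_result
#' @export
tidy.dnet_result <- function(x, ...) {
  ut <- which(upper.tri(x$combined), arr.ind = TRUE)
  rej_keys <- paste(x$rejected[, 1L], x$rejected[, 2L])
  tibble::tibble(
    var_i = x$variable_ids[ut[, 1L]],
    var_j = x$variable_ids[ut[, 2L]],
    statistic = x$combined[ut],
    t_value = x$t_stats[ut],
    rejected = paste(ut[, 1L], ut[, 2L]) %in% rej_keys
  ) |>
    dplyr::arrange(dplyr::desc(.data$t_value))
}

#' One-row summary of a differential-network test
#'
#' @param x A `dnet_result`.
#' @param ... Unused.
#' @return A tibble with the FDR level, threshold (and whether the
#'   fallback threshold was used), rejection count, empirical null
#'   fraction and correction constant.
#' @method glance dnet_result
#' @export
glance.dnet_result <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_labels),
    p = length(x$variable_ids),
    n_tests = length(x$variable_ids) * (length(x$variable_ids) - 1) / 2,
    alpha0 = x$alpha0,
    threshold = x$threshold,
    fallback = x$fallback,
    n_rejected = nrow(x$rejected),
    p0 = x$constants$P0,
    p0_hat = x$constants$P0_hat,
    correction_a = x$constants$A
  )
}

#' Tidy a simulation performance report
#'
#' @param x A `dnet_perf`.
#' @param ... Unused.
#' @return A tibble with columns `alpha`, `efdr`, `power`.
#' @method tidy dnet_perf
#' @export
tidy.dnet_perf <- function(x, ...) x$summary

#' @method glance dnet_perf
#' @export
glance.dnet_perf <- function(x, ...) {
  tibble::tibble(graph_type = x$model$graph_type, p = x$model$p,
                 n1 = x$n1, n2 = x$n2, reps = x$reps, oracle = x$oracle,
                 n_differential = nrow(x$model$differential_edges))
}

#' Plot the normal-scale statistics of a test against the FDR threshold
#'
#' Sorted normal-scale statistics with the rejection threshold drawn as a
#' horizontal line; called edges are highlighted.
#'
#' @param object A `dnet_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnet_result <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::arrange(.data$t_value) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$t_value,
                                   colour = .data$rejected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "edge rank", y = "normal-scale statistic T",
                  colour = "differential",
                  title = sprintf("FDR threshold %.3f at alpha0 = %.2f",
                                  object$threshold, object$alpha0)) +
    ggplot2::theme_minimal()
}

#' Plot eFDR and power curves of a simulation report
#'
#' Empirical FDR against the nominal level (with the y = x reference
#' line) and power against the nominal level, as two facets.
#'
#' @param object A `dnet_perf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnet_perf <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary, c("efdr", "power"),
                            names_to = "metric", values_to = "value")
  ref <- tibble::tibble(metric = "efdr", alpha = object$summary$alpha,
                        value = object$summary$alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$value)) +
    ggplot2::geom_line(data = ref, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "nominal FDR level", y = NULL,
                  title = sprintf("%s graph, p = %d, %d reps",
                                  object$model$graph_type, object$model$p,
                                  object$reps)) +
    ggplot2::theme_minimal()
}

#' Write the artifacts of a differential-network test to disk
#'
#' Writes the edge table (`edges.tsv`), the full matrix of normal-scale
#' statistics (`t_matrix.tsv`) and a reproducibility record
#' (`metadata.json`: FDR level, threshold, constants, per-class
#' truncation levels and selected penalties) into a directory.
#'
#' @param result A `dnet_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dnet_result <- function(result, dir) {
  if (!inherits(result, "dnet_result")) {
    stop("`result` must be a `dnet_result`", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(result), file.path(dir, "edges.tsv"))
  t_df <- tibble::as_tibble(result$t_stats, rownames = "variable")
  readr::write_tsv(t_df, file.path(dir, "t_matrix.tsv"))
  meta <- list(
    alpha0 = result$alpha0, threshold = result$threshold,
    fallback = result$fallback, constants = result$constants,
    class_labels = result$class_labels,
    n_per_class = result$n_per_class, delta_n = result$delta_n,
    weights = result$weights, config = result$config,
    lambda_used = lapply(result$fits, function(f) f$lambda_used),
    n_rejected = nrow(result$rejected)
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
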