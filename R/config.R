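#' Run configuration for the command-line interface
#'
#' Validated bundle of the tunables a full run needs, serialisable to and
#' from plain JSON so results can be reproduced from the recorded file.
#'
#' @param alpha0 Nominal FDR level in (0, 1).
#' @param method Node-wise solver, `"lasso"` or `"dantzig"`.
#' @param gram_source `"adjusted_spearman"` or `"imputed"`.
#' @param n_lambdas AIC grid size (at least 2).
#' @param delta_override Optional truncation-level override for the
#'   Winsorized transform.
#' @param seed Integer seed.
#' @param weights Optional positive weights for the K > 2 reference law.
#' @param output_dir Directory run artifacts are written to.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(alpha0 = 0.05, method = "lasso",
                       gram_source = "adjusted_spearman", n_lambdas = 20L,
                       delta_override = NULL, seed = 1L, weights = NULL,
                       output_dir = ".") {
  check_scalar_prob(alpha0, "alpha0")
  method <- match.arg(method, c("lasso", "dantzig"))
  gram_source <- match.arg(gram_source, c("adjusted_spearman", "imputed"))
  if (n_lambdas < 2) stop("`n_lambdas` must be at least 2", call. = FALSE)
  if (!is.null(delta_override)) {
    check_scalar_prob(delta_override, "delta_override")
  }
  if (!is.null(weights) && any(weights <= 0)) {
    stop("`weights` must be positive", call. = FALSE)
  }
  structure(
    list(alpha0 = alpha0, method = method, gram_source = gram_source,
         n_lambdas = as.integer(n_lambdas), delta_override = delta_override,
         seed = as.integer(seed), weights = weights,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a `run_config`", call. = FALSE)
  }
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}
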