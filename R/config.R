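#' Run configuration
#'
#' Flat key-value configuration shared by the command-line surface.  All
#' probability-like thresholds live in (0, 1).
#'
#' @param threshold positive-call probability threshold (default 0.5).
#' @param forced_threshold minimum argmax probability for a forced call
#'   (default 0.1).
#' @param rho_threshold minimum Spearman correlation for an SSP assignment
#'   (default 0.1).
#' @param n_folds split-sample cross-validation folds (default 7).
#' @param vdv_alpha significance level of van der Voet's test (default 0.10).
#' @param kappa_scheme kappa weight scheme (default "linear").
#' @param seed integer seed; required by stochastic operations.
#' @param center_only skip per-gene scaling (centring always applied).
#' @param max_k largest candidate component count for auto selection.
#' @return A `run_config` list.
#' @export
run_config <- function(threshold = 0.5, forced_threshold = 0.1,
                       rho_threshold = 0.1, n_folds = 7, vdv_alpha = 0.10,
                       kappa_scheme = "linear", seed = NULL,
                       center_only = FALSE, max_k = 3) {
  for (v in c(threshold, forced_threshold, rho_threshold, vdv_alpha))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)")
  structure(list(threshold = threshold, forced_threshold = forced_threshold,
                 rho_threshold = rho_threshold, n_folds = n_folds,
                 vdv_alpha = vdv_alpha, kappa_scheme = kappa_scheme,
                 seed = seed, center_only = center_only, max_k = max_k),
            class = "run_config")
}

#' Read / write a flat YAML configuration
#'
#' @param path YAML file of flat keys matching the [run_config()] arguments.
#' @return `read_config`: a `run_config` with file values overriding
#'   defaults.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a `run_config` to write.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, NA)], path)
  invisible(path)
}
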