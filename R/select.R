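#' Split-sample cross-validation PRESS over candidate component counts
#'
#' Observations are assigned to folds systematically by input order
#' (observation i goes to fold `(i - 1) mod n_folds + 1`).  For each fold a
#' PLS model is refit on the remainder and the held-out responses are
#' predicted; `PRESS(k)` is the sum of squared cross-validated residuals at k
#' components.
#'
#' @param data a [centered_matrix()].
#' @param max_k largest candidate component count.
#' @param n_folds number of folds (>= 2); default 7, the systematic
#'   split-sample convention.
#' @return A `cv_result` list: `k_candidates`, `press`, `residuals`
#'   (observations x candidates matrix of cross-validated residuals),
#'   `k_min_press`.
#' @export
split_sample_cv <- function(data, max_k, n_folds = 7) {
  stopifnot(inherits(data, "centered_matrix"))
  n <- nrow(data$X0)
  if (n_folds < 2) stop("n_folds must be >= 2")
  n_folds <- min(n_folds, n)
  fold <- ((seq_len(n) - 1L) %% n_folds) + 1L
  min_train <- n - max(table(fold))
  if (max_k > min_train - 1L)
    stop("max_k = ", max_k, " exceeds smallest training fold size - 1 (",
         min_train - 1L, ")")

  residuals <- matrix(NA_real_, n, max_k)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    y_tr <- data$Y0[tr]
    if (stats::sd(y_tr) == 0)
      stop("fold ", f, ": training response is constant ",
           "(a fold lost all members of one class)")
    held_y <- data$Y0[!tr]
    if (length(unique(data$Y0)) == 2L &&
        length(unique(held_y)) == 1L && length(held_y) > 1L)
      warning("fold ", f, " holds out members of a single response class")
    fit <- fit_pls(centered_matrix(data$X0[tr, , drop = FALSE], y_tr,
                                   check = FALSE), k = max_k)
    for (k in seq_len(max_k)) {
      beta <- pls_beta(fit, k)
      pred <- drop(data$X0[!tr, , drop = FALSE] %*% beta)
      residuals[!tr, k] <- held_y - pred
    }
  }
  press <- colSums(residuals^2)
  structure(
    list(k_candidates = seq_len(max_k), press = press, residuals = residuals,
         k_min_press = which.min(press), fold = fold),
    class = "cv_result")
}

#' van der Voet's randomization test on paired cross-validated residuals
#'
#' Compares a candidate model with a reference model through the statistic
#' `C = sum(r_k^2 - r_ref^2)` over paired cross-validated residuals.  The
#' null distribution is generated by independently negating each paired
#' difference: all `2^n` sign patterns are enumerated when `n <= 20`,
#' otherwise Monte Carlo with `n_randomizations` draws is used.  The p-value
#' is the proportion of randomized `|C*| >= |C|` (with add-one smoothing in
#' the Monte Carlo case).
#'
#' @param residuals_k cross-validated residuals of the candidate model.
#' @param residuals_ref residuals of the reference (minimal-PRESS) model,
#'   same observations, same order.
#' @param n_randomizations Monte Carlo draws when enumeration is infeasible.
#' @param seed integer seed for the Monte Carlo draws.
#' @param force_monte_carlo use the Monte Carlo path even when enumeration is
#'   feasible (mainly to validate the sampler against the exact answer).
#' @return p-value in \[0, 1\].
#' @export
van_der_voet_test <- function(residuals_k, residuals_ref,
                              n_randomizations = 2000, seed = NULL,
                              force_monte_carlo = FALSE) {
  if (length(residuals_k) != length(residuals_ref))
    stop("residual vectors must be paired (equal length)")
  d <- residuals_k^2 - residuals_ref^2
  n <- length(d)
  C <- sum(d)
  if (all(d == 0)) return(1)
  if (n <= 20L && !force_monte_carlo) {
    # full enumeration of the 2^n sign patterns, built incrementally
    Cstar <- 0
    for (di in d) Cstar <- c(Cstar - di, Cstar + di)
    return(mean(abs(Cstar) >= abs(C) - 1e-12))
  }
  if (is.null(seed)) stop("seed required for Monte Carlo randomization")
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_randomizations, replace = TRUE),
                    nrow = n_randomizations)
    Cstar <- drop(signs %*% d)
    (sum(abs(Cstar) >= abs(C) - 1e-12) + 1L) / (n_randomizations + 1L)
  })
}

#' Choose the number of latent components
#'
#' Implements the parsimony rule: the fewest components whose cross-validated
#' residuals are not significantly different (van der Voet's test) from those
#' of the minimal-PRESS candidate.
#'
#' @param cv a `cv_result` from [split_sample_cv()].
#' @param alpha significance level for van der Voet's test (default 0.10).
#' @param n_randomizations,seed passed to [van_der_voet_test()].
#' @return The `cv_result` augmented with `p_values` and `k_selected`.
#' @export
select_components <- function(cv, alpha = 0.10, n_randomizations = 2000,
                              seed = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  ref <- cv$residuals[, cv$k_min_press]
  p <- vapply(cv$k_candidates, function(k) {
    if (k == cv$k_min_press) return(1)
    van_der_voet_test(cv$residuals[, k], ref, n_randomizations, seed)
  }, numeric(1))
  admissible <- which(p >= alpha | cv$k_candidates == cv$k_min_press)
  cv$p_values <- p
  cv$k_selected <- min(admissible)
  cv
}

#' Write a component-selection report as TSV
#'
#' @param cv a `cv_result` that has been through [select_components()].
#' @param path output file.
#' @export
write_cv_report <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  df <- data.frame(k = cv$k_candidates, PRESS = cv$press,
                   p_value = if (!is.null(cv$p_values)) cv$p_values else NA,
                   selected = cv$k_candidates ==
                     if (!is.null(cv$k_selected)) cv$k_selected else NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
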