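#' Canonical intrinsic subtype order
#'
#' The five PAM50 intrinsic molecular subtypes in the canonical order used
#' throughout the package, plus the reject label.
#' @export
SUBTYPES <- c("Basal-like", "HER2-enriched", "Luminal-A", "Luminal-B",
              "Normal breast-like")

#' @rdname SUBTYPES
#' @export
UNCLASSIFIED <- "Unclassified"

#' Fit a one-versus-rest subtype classifier
#'
#' Restricts the expression matrix to the subtype's gene panel, centres and
#' scales each gene, extracts latent gene components by PLS (the component
#' count chosen by cross-validated PRESS plus van der Voet's test when
#' `k = "auto"`), and fits a binary logistic regression on the component
#' scores.  The predicted probability of subtype membership is
#' `1 / (1 + exp(-(b0 + b1 x1 + ... + bk xk)))` over the k scores.
#'
#' Perfect separation of the logistic fit is handled by a ridge-stabilised
#' IRLS fallback (penalty `1e-6` on the coefficients) with a message.
#'
#' @param x an [expression_matrix()] (complete; log scale).
#' @param labels binary vector (0/1 or logical), one per sample: membership
#'   of the target subtype.
#' @param panel character vector of panel gene symbols, or a `gene_panel`.
#' @param k component count, or `"auto"` for PRESS + van der Voet selection.
#' @param subtype_name label stored on the classifier.
#' @param threshold positive-call probability threshold (default 0.5).
#' @param center_only skip the per-gene scaling (centring always applied).
#' @param max_k largest candidate when `k = "auto"`.
#' @param n_folds,vdv_alpha,seed cross-validation controls for `k = "auto"`.
#' @param .min_per_class smallest admissible class size (internal:
#'   leave-one-out refits relax it to 2).
#' @return A `subtype_classifier`: panel, per-gene training mean/sd, fitted
#'   `pls_model`, logistic coefficients (`beta0`, `betas`), `threshold`.
#' @export
fit_classifier <- function(x, labels, panel, k = "auto",
                           subtype_name = "subtype", threshold = 0.5,
                           center_only = FALSE, max_k = 3, n_folds = 7,
                           vdv_alpha = 0.10, seed = NULL,
                           .min_per_class = 3) {
  stopifnot(inherits(x, "expression_matrix"))
  if (inherits(panel, "gene_panel")) {
    if (identical(subtype_name, "subtype")) subtype_name <- panel$subtype_name
    panel <- panel$gene_ids
  }
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (length(y) != ncol(x$values))
    stop("labels length != sample count")
  if (min(table(factor(y, levels = c(0, 1)))) < .min_per_class)
    stop("fewer than ", .min_per_class, " samples in one class")

  sub <- subset_genes(x, panel)
  std <- standardize_genes(sub, center_only = center_only)
  X0 <- t(std$values)                         # samples x genes
  y0 <- scale(y)[, 1]                         # centred & scaled response
  data <- centered_matrix(X0, y0)

  max_k <- min(max_k, nrow(X0) - 1L, ncol(X0))
  if (identical(k, "auto")) {
    cv <- split_sample_cv(data, max_k = max_k, n_folds = n_folds)
    cv <- select_components(cv, alpha = vdv_alpha, seed = seed)
    k <- cv$k_selected
  } else {
    cv <- NULL
    k <- as.integer(k)
  }
  pls <- fit_pls(data, k = k)
  lr <- fit_logistic(pls$T, y)

  structure(
    list(subtype_name = subtype_name, panel = panel,
         gene_means = attr(std, "gene_means"),
         gene_sds = attr(std, "gene_sds"),
         center_only = center_only,
         pls = pls, lr = lr, threshold = threshold, cv = cv,
         labels = y),
    class = "subtype_classifier")
}

#' @export
print.subtype_classifier <- function(x, ...) {
  cat(sprintf("subtype_classifier '%s': %d panel genes, k = %d, threshold %g\n",
              x$subtype_name, length(x$panel), x$pls$k, x$threshold))
  invisible(x)
}

#' Predicted subtype-membership probability for new samples
#'
#' Applies the training centring/scaling to the panel genes, projects onto
#' the latent components, and evaluates the logistic model
#' `(1 + exp(-(b0 + b1 x1 + ... + bk xk)))^{-1}`.
#'
#' @param clf a `subtype_classifier`.
#' @param x an [expression_matrix()] containing the panel genes.
#' @return Named numeric vector of probabilities in (0, 1), one per sample.
#' @export
predict_probability <- function(clf, x) {
  stopifnot(inherits(clf, "subtype_classifier"),
            inherits(x, "expression_matrix"))
  scores <- classifier_scores(clf, x)
  eta <- drop(clf$lr$beta0 + scores %*% clf$lr$betas)
  pr <- stats::plogis(eta)
  # keep probabilities strictly inside (0, 1)
  pr <- pmin(pmax(pr, .Machine$double.xmin), 1 - .Machine$double.eps)
  stats::setNames(pr, x$sample_ids)
}

# internal: centre/scale new samples by the training parameters and project
classifier_scores <- function(clf, x) {
  sub <- subset_genes(x, clf$panel)
  v <- sub$values - clf$gene_means[clf$panel]
  if (!clf$center_only) {
    sds <- clf$gene_sds[clf$panel]
    sds[is.na(sds)] <- 1
    v <- v / sds
  }
  project_pls(clf$pls, t(v))
}

#' Leave-one-out cross-validated probabilities
#'
#' For each sample, the whole pipeline — per-gene centring/scaling, PLS with
#' a fixed component count, logistic regression — is refit on the remaining
#' n - 1 samples and the held-out sample predicted.  The component count is
#' not re-selected per fold.
#'
#' @inheritParams fit_classifier
#' @param k fixed component count (select it once beforehand; `"auto"` here
#'   selects on the full data first, then holds it fixed).
#' @return Named numeric vector of cross-validated probabilities.
#' @export
loocv_probabilities <- function(x, labels, panel, k, subtype_name = "subtype",
                                center_only = FALSE, ...) {
  stopifnot(inherits(x, "expression_matrix"))
  if (inherits(panel, "gene_panel")) panel <- panel$gene_ids
  y <- as.numeric(labels)
  n <- ncol(x$values)
  if (min(table(factor(y, levels = c(0, 1)))) < 3)
    stop("fewer than 3 samples in one class")
  if (identical(k, "auto")) {
    full <- fit_classifier(x, y, panel, k = "auto",
                           center_only = center_only, ...)
    k <- full$pls$k
  }
  pr <- numeric(n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    if (length(unique(y[tr_idx])) < 2L)
      stop("leave-one-out fold ", i, " has a single-class training set")
    tr <- expression_matrix(x$values[, tr_idx, drop = FALSE],
                            gene_ids = x$gene_ids,
                            sample_ids = x$sample_ids[tr_idx])
    # class-size floor applies to the full data, not the n - 1 refits
    clf <- fit_classifier(tr, y[tr_idx], panel, k = k,
                          subtype_name = subtype_name,
                          center_only = center_only, .min_per_class = 2)
    ho <- expression_matrix(x$values[, i, drop = FALSE],
                            gene_ids = x$gene_ids,
                            sample_ids = x$sample_ids[i])
    pr[i] <- predict_probability(clf, ho)
  }
  stats::setNames(pr, x$sample_ids)
}

#' Binary classifier performance metrics
#'
#' Confusion-matrix metrics at the given probability threshold, the area
#' under the ROC curve by the midrank (Mann-Whitney) statistic, and the
#' Nagelkerke pseudo R-squared.
#'
#' @param probabilities predicted probabilities in (0, 1).
#' @param labels binary (0/1) truth.
#' @param threshold positive-call threshold (default 0.5).
#' @return List: `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `adjusted_r2`, and the 2x2 `confusion` table.  AUC and sensitivity are
#'   `NA` when a class is absent.
#' @export
classifier_metrics <- function(probabilities, labels, threshold = 0.5) {
  y <- as.numeric(labels)
  p <- as.numeric(probabilities)
  stopifnot(length(y) == length(p))
  pos <- y == 1
  call <- p > threshold
  tp <- sum(call & pos); fn <- sum(!call & pos)
  fp <- sum(call & !pos); tn <- sum(!call & !pos)
  acc <- (tp + tn) / length(y)
  sens <- if (sum(pos) > 0) tp / sum(pos) else NA_real_
  spec <- if (sum(!pos) > 0) tn / sum(!pos) else NA_real_

  auc <- if (sum(pos) == 0 || sum(!pos) == 0) NA_real_ else {
    r <- rank(p)                               # midranks handle ties
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }

  # Nagelkerke pseudo R^2 from the predicted probabilities
  eps <- 1e-12
  pc <- pmin(pmax(p, eps), 1 - eps)
  ll1 <- sum(y * log(pc) + (1 - y) * log(1 - pc))
  p0 <- mean(y)
  ll0 <- if (p0 %in% c(0, 1)) 0 else
    sum(y * log(p0) + (1 - y) * log(1 - p0))
  n <- length(y)
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  r2 <- if (ll0 == 0) NA_real_ else cox_snell / (1 - exp(2 * ll0 / n))

  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c("pos", "neg"),
                                      call = c("pos", "neg")))
  confusion[2, 1] <- fp; confusion[1, 2] <- fn  # truth rows, call columns
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       auc = auc, adjusted_r2 = r2, confusion = confusion)
}

# internal: logistic regression of a binary response on PLS scores.
# stats::glm IRLS first; on non-convergence or separation, a ridge-stabilised
# IRLS (penalty on all coefficients) keeps estimates finite.
fit_logistic <- function(scores, y, ridge = 1e-6) {
  scores <- as.matrix(scores)
  df <- data.frame(y = y, scores)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep && fit$converged) {
    cf <- stats::coef(fit)
    return(list(beta0 = unname(cf[1]), betas = unname(cf[-1]),
                separation = FALSE, model = "glm"))
  }
  message("logistic fit separated or failed to converge; ",
          "using ridge-stabilised IRLS (penalty ", ridge, ")")
  cf <- ridge_irls(cbind(1, scores), y, lambda = ridge)
  list(beta0 = cf[1], betas = cf[-1], separation = TRUE, model = "ridge_irls")
}

# internal: IRLS for penalised logistic regression; the intercept is
# penalised too (the penalty is tiny and only there to bound separation)
ridge_irls <- function(X, y, lambda = 1e-6, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, w * X) + diag(lambda, ncol(X))
    bnew <- solve(H, crossprod(X, w * z))
    if (max(abs(bnew - beta)) < tol) { beta <- drop(bnew); break }
    beta <- drop(bnew)
  }
  beta
}

#' Per-classifier performance report
#'
#' One row per fitted classifier, mirroring the standard report layout:
#' component count, cumulative X- and Y-variance explained, Nagelkerke
#' R-squared, AUC, accuracy, sensitivity, specificity.  Metrics are computed
#' from the supplied probabilities (cross-validated ones are the honest
#' choice on training data).
#'
#' @param classifiers list of `subtype_classifier` objects.
#' @param probabilities list of probability vectors, parallel to
#'   `classifiers`.
#' @param labels list of binary truth vectors, parallel to `classifiers`.
#' @return A data frame, one row per classifier.
#' @export
classifier_report <- function(classifiers, probabilities, labels) {
  rows <- lapply(seq_along(classifiers), function(i) {
    clf <- classifiers[[i]]
    m <- classifier_metrics(probabilities[[i]], labels[[i]], clf$threshold)
    data.frame(subtype = clf$subtype_name,
               n_components = clf$pls$k,
               x_var_explained = clf$pls$x_cum_var[clf$pls$k],
               y_var_explained = clf$pls$y_cum_var[clf$pls$k],
               adjusted_r2 = m$adjusted_r2, auc = m$auc,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity)
  })
  do.call(rbind, rows)
}
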