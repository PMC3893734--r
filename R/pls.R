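#' Centred predictor/response pair for PLS
#'
#' Bundles a column-centred (and usually scaled) predictor matrix `X0`
#' (samples x genes) with a centred response column `Y0`.  PLS extracts
#' latent factors maximizing the covariance `X0' Y0`.
#'
#' @param X0 numeric matrix, samples in rows, genes in columns, columns
#'   centred.
#' @param Y0 numeric vector (one response per sample), centred.
#' @param check verify the centring invariant (column means 0 within 1e-10).
#' @return An object of class `centered_matrix`.
#' @export
centered_matrix <- function(X0, Y0, check = TRUE) {
  X0 <- as.matrix(X0)
  Y0 <- as.numeric(Y0)
  if (nrow(X0) != length(Y0))
    stop("X0 rows (", nrow(X0), ") != Y0 length (", length(Y0), ")")
  if (check) {
    if (max(abs(colMeans(X0))) > 1e-10)
      stop("X0 columns are not centred")
    if (abs(mean(Y0)) > 1e-10)
      stop("Y0 is not centred")
  }
  structure(list(X0 = X0, Y0 = Y0), class = "centered_matrix")
}

#' Fit a single-response PLS model by NIPALS
#'
#' Latent gene components are extracted one at a time.  For a single
#' response, component a's weight vector is the normalized cross-covariance
#' of the current residual matrices, `w = X' y / ||X' y||`; x-scores are
#' `t = X w`, x-loadings `p = X' t / (t' t)`, the y-loading
#' `c = y' t / (t' t)`, and both `X` and `y` are deflated by the rank-one
#' fits `t p'` and `t c` before the next component.  Weight vectors have unit
#' Euclidean norm; successive score vectors are orthogonal.  Each weight
#' vector's sign is fixed so that its largest-magnitude entry is positive.
#'
#' @param data a [centered_matrix()].
#' @param k number of latent components (>= 1, <= min(samples - 1, genes)).
#' @return An object of class `pls_model` with elements `k`, `W` (genes x k
#'   weights), `P` (x-loadings), `C` (y-loadings, length k), `T` (x-scores),
#'   `U` (y-scores), `R` (rotation such that `X0 %*% R = T`),
#'   `x_var_explained`, `y_var_explained` (per-component and cumulative
#'   fractions) and `gene_order`.
#' @export
fit_pls <- function(data, k) {
  stopifnot(inherits(data, "centered_matrix"))
  X <- data$X0
  y <- data$Y0
  n <- nrow(X); p <- ncol(X)
  if (k < 1) stop("k must be >= 1")
  if (k > min(n - 1L, p))
    stop("k = ", k, " exceeds min(samples - 1, genes) = ", min(n - 1L, p))
  ssx_tot <- sum(X^2)
  ssy_tot <- sum(y^2)

  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Tm <- matrix(0, n, k); U <- matrix(0, n, k)
  Cv <- numeric(k)
  xve <- numeric(k); yve <- numeric(k)

  for (a in seq_len(k)) {
    w <- crossprod(X, y)                      # X' y, the cross-covariance
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("no predictive structure: response orthogonal to all predictors",
           if (a > 1L) paste0(" after ", a - 1L, " component(s)") else "")
    w <- w / nw
    # sign convention: largest-magnitude weight entry positive
    if (w[which.max(abs(w))] < 0) w <- -w
    tt <- drop(X %*% w)
    t2 <- sum(tt^2)
    pp <- drop(crossprod(X, tt)) / t2
    cc <- sum(y * tt) / t2
    uu <- y                                   # y-scores: u = Y0 q with q = 1

    X <- X - tcrossprod(tt, pp)
    y <- y - tt * cc
    W[, a] <- w; P[, a] <- pp; Cv[a] <- cc
    Tm[, a] <- tt; U[, a] <- uu
    xve[a] <- t2 * sum(pp^2) / ssx_tot
    yve[a] <- t2 * cc^2 / ssy_tot
  }
  R <- W %*% solve(crossprod(P, W))           # rotation: X0 R = T
  structure(
    list(k = k, W = W, P = P, C = Cv, T = Tm, U = U, R = R,
         x_var_explained = xve, y_var_explained = yve,
         x_cum_var = cumsum(xve), y_cum_var = cumsum(yve),
         gene_order = colnames(data$X0)),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d component(s), %d genes\n", x$k, nrow(x$W)))
  cat(sprintf("  cumulative X-variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$x_cum_var), collapse = ", ")))
  cat(sprintf("  cumulative Y-variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$y_cum_var), collapse = ", ")))
  invisible(x)
}

#' Project new samples onto a fitted PLS model
#'
#' Scores for new observations are a fixed linear transform of the (already
#' centred/scaled) expression values: `T_new = X_new R` where
#' `R = W (P' W)^{-1}` corrects the weights for deflation, so that projecting
#' the training matrix reproduces the training scores.
#'
#' @param model a [pls_model()].
#' @param new_X0 numeric matrix (samples x genes) whose columns follow
#'   `model$gene_order` and were centred/scaled by the training parameters.
#' @return Score matrix, samples x k.
#' @export
project_pls <- function(model, new_X0) {
  stopifnot(inherits(model, "pls_model"))
  new_X0 <- as.matrix(new_X0)
  if (!is.null(model$gene_order) && !is.null(colnames(new_X0))) {
    missing <- setdiff(model$gene_order, colnames(new_X0))
    if (length(missing) > 0)
      stop("genes absent from new data: ", paste(missing, collapse = ", "))
    new_X0 <- new_X0[, model$gene_order, drop = FALSE]
  }
  if (ncol(new_X0) != nrow(model$W))
    stop("new data has ", ncol(new_X0), " genes; model expects ",
         nrow(model$W))
  new_X0 %*% model$R
}

#' Per-component and cumulative variance-explained fractions
#'
#' Fractions of the total centred sum of squares of the predictors and the
#' response removed by each deflation step of the NIPALS fit.
#'
#' @param model a [pls_model()].
#' @return A data frame with one row per component: `component`, `x_var`,
#'   `x_cum`, `y_var`, `y_cum`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  data.frame(component = seq_len(model$k),
             x_var = model$x_var_explained,
             x_cum = model$x_cum_var,
             y_var = model$y_var_explained,
             y_cum = model$y_cum_var)
}

# internal: regression coefficients of the centred response on the centred
# predictors implied by the first k components: Y0_hat = X0 %*% beta
pls_beta <- function(model, k = model$k) {
  model$R[, seq_len(k), drop = FALSE] %*% model$C[seq_len(k)]
}
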