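# Shared fixture builders: everything is generated in code at test time.

# small expression_matrix from a genes x samples numeric matrix
make_expr <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  expression_matrix(values, gene_ids = genes, sample_ids = samples)
}

# random centred predictor/response pair (samples x genes)
random_centered <- function(n, p, seed) {
  set.seed(seed)
  X0 <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  colnames(X0) <- sprintf("G%02d", seq_len(p))
  Y0 <- drop(scale(rnorm(n), scale = FALSE))
  centered_matrix(X0, Y0)
}

# independent NIPALS oracle: the classical iterative two-block algorithm,
# structured differently from the package's single-pass PLS1 closed form
nipals_oracle <- function(X, y, k, tol = 1e-12, max_iter = 500) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, k); P <- matrix(0, p, k); Tm <- matrix(0, n, k)
  Cv <- numeric(k)
  for (a in seq_len(k)) {
    u <- y
    w_old <- rep(Inf, p)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(X %*% w)
      cc <- sum(y * tt) / sum(tt^2)
      u <- y / cc
      if (max(abs(w - w_old)) < tol) break
      w_old <- w
    }
    if (w[which.max(abs(w))] < 0) { w <- -w; tt <- -tt; cc <- -cc }
    pp <- drop(crossprod(X, tt)) / sum(tt^2)
    X <- X - tcrossprod(tt, pp)
    y <- y - tt * cc
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; Cv[a] <- cc
  }
  list(W = W, P = P, T = Tm, C = Cv)
}

# two well-separated clusters on a small gene panel
two_cluster_cohort <- function(n_pos = 10, n_neg = 10, p = 6, shift = 3,
                               seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(p * (n_pos + n_neg)), p)
  vals[, seq_len(n_pos)] <- vals[, seq_len(n_pos)] + shift
  list(x = make_expr(vals), y = rep(c(1, 0), c(n_pos, n_neg)),
       panel = sprintf("G%02d", seq_len(p)))
}
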