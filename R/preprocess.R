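#' Collapse probesets to genes by maximal inter-quartile range
#'
#' When a platform measures a gene with several probesets, only the most
#' variable probeset — measured by the inter-quartile range (IQR) across all
#' arrays — is retained for that gene.  Genes with a single probeset pass
#' through unchanged.  IQR ties keep the first probeset in input order and
#' emit a warning.
#'
#' @param x an [expression_matrix()] whose rows are probesets.
#' @param probe_to_gene named character vector (or two-column data frame)
#'   mapping every probeset row to a gene symbol.
#' @return An [expression_matrix()] with one row per gene.  Quantiles use
#'   linear interpolation (`stats::quantile` type 7).
#' @export
collapse_by_iqr <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "expression_matrix"))
  if (nrow(x$values) == 0) stop("empty expression matrix")
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2]]),
                                     as.character(probe_to_gene[[1]]))
  probes <- if (!is.null(x$probeset_ids)) x$probeset_ids else x$gene_ids
  unmapped <- setdiff(probes, names(probe_to_gene))
  if (length(unmapped) > 0)
    stop("probesets without a gene mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  genes <- unname(probe_to_gene[probes])

  iqr <- apply(x$values, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)  # all-missing: ineligible
    stats::quantile(v, 0.75, names = FALSE) -
      stats::quantile(v, 0.25, names = FALSE)
  })

  keep <- integer(0)
  for (g in unique(genes)) {
    rows <- which(genes == g)
    vals <- iqr[rows]
    if (length(rows) == 1L) {
      if (is.na(vals))
        stop("all probesets for gene ", g,
             " are fully missing (IQR undefined)")
      keep <- c(keep, rows); next
    }
    if (all(is.na(vals)))
      stop("all probesets for gene ", g, " are fully missing (IQR undefined)")
    best <- max(vals, na.rm = TRUE)
    hits <- rows[!is.na(vals) & vals == best]
    if (length(hits) > 1L)
      warning("IQR tie for gene ", g, "; keeping first probeset in input order")
    keep <- c(keep, hits[1L])
  }
  expression_matrix(x$values[keep, , drop = FALSE],
                    gene_ids = genes[keep], sample_ids = x$sample_ids,
                    probeset_ids = probes[keep])
}

#' Centre (and scale) every gene across samples
#'
#' Each gene row is mean-centred; unless `center_only` it is also divided by
#' its sample standard deviation (denominator n - 1) so every row has mean 0
#' and standard deviation 1.  Zero-variance rows are centred only and their
#' identifiers returned in the `zero_variance` attribute.
#'
#' @param x an [expression_matrix()] with no missing values.
#' @param center_only if `TRUE`, skip the division by the standard deviation.
#' @return The standardized [expression_matrix()], with attributes
#'   `gene_means`, `gene_sds` (the training parameters, usable to standardize
#'   new samples) and `zero_variance` (character vector of flagged genes).
#' @export
standardize_genes <- function(x, center_only = FALSE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (anyNA(x$values))
    stop("standardize_genes requires a complete matrix; run impute_em first")
  mu <- rowMeans(x$values)
  v <- x$values - mu
  sds <- apply(x$values, 1L, stats::sd)
  flat <- sds == 0 | is.na(sds)
  if (!center_only) {
    div <- ifelse(flat, 1, sds)
    v <- v / div
  }
  out <- expression_matrix(v, gene_ids = x$gene_ids,
                           sample_ids = x$sample_ids)
  attr(out, "gene_means") <- stats::setNames(mu, x$gene_ids)
  attr(out, "gene_sds") <- stats::setNames(ifelse(flat, NA_real_, sds),
                                           x$gene_ids)
  attr(out, "zero_variance") <- x$gene_ids[flat]
  if (any(flat))
    message(sum(flat), " zero-variance gene(s) centred only: ",
            paste(utils::head(x$gene_ids[flat], 5), collapse = ", "))
  out
}

#' Impute missing expression values by expectation-maximization
#'
#' Missing entries of each gene are first initialized to that gene's mean
#' over its non-missing values.  The completed matrix is then repeatedly fit
#' with a low-rank latent-factor model and the missing cells replaced by the
#' model reconstruction (scores x loadings), until the largest absolute
#' change of an imputed cell drops below `tol` or `max_iter` is reached.
#' Observed entries are never altered.
#'
#' When a binary `labels` vector is supplied the reconstruction model is a
#' PLS fit with that response (the situation during classifier training);
#' otherwise a principal-component reconstruction is used.
#'
#' @param x an [expression_matrix()]; may contain `NA`s.
#' @param n_components rank of the reconstruction model.
#' @param tol convergence tolerance on imputed values.
#' @param max_iter iteration cap.
#' @param labels optional binary (0/1) response per sample enabling the PLS
#'   reconstruction.
#' @return The completed [expression_matrix()] with attributes `converged`,
#'   `iterations` and `max_change`.
#' @export
impute_em <- function(x, n_components = 2, tol = 1e-6, max_iter = 100,
                      labels = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  vals <- x$values
  miss <- is.na(vals)
  if (!any(miss)) {
    attr(x, "converged") <- TRUE
    attr(x, "iterations") <- 0L
    attr(x, "max_change") <- 0
    return(x)
  }
  all_missing <- rowSums(!miss) == 0
  if (any(all_missing))
    stop("gene(s) fully missing, cannot impute: ",
         paste(x$gene_ids[all_missing], collapse = ", "))

  gene_means <- rowMeans(vals, na.rm = TRUE)
  filled <- vals
  filled[miss] <- gene_means[row(vals)[miss]]

  n_components <- min(n_components, nrow(vals) - 1L, ncol(vals) - 1L)
  n_components <- max(n_components, 1L)
  converged <- FALSE
  delta <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    recon <- reconstruct_low_rank(filled, n_components, labels)
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- expression_matrix(filled, gene_ids = x$gene_ids,
                           sample_ids = x$sample_ids,
                           probeset_ids = x$probeset_ids)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "max_change") <- delta
  out
}

# internal: rank-k reconstruction of a genes x samples matrix.
# Works on the samples x genes orientation with per-gene centring; either a
# PCA (SVD) reconstruction or, when a response is available, a PLS one.
reconstruct_low_rank <- function(vals, k, labels = NULL) {
  Xt <- t(vals)                       # samples x genes
  mu <- colMeans(Xt)
  Xc <- sweep(Xt, 2L, mu)
  if (!is.null(labels)) {
    y <- as.numeric(labels)
    y0 <- y - mean(y)
    if (stats::sd(y) > 0 && sqrt(sum(crossprod(Xc, y0)^2)) > 1e-12) {
      fit <- fit_pls(centered_matrix(Xc, y0, check = FALSE),
                     k = min(k, nrow(Xc) - 1L, ncol(Xc)))
      rec <- fit$T %*% t(fit$P)
      return(t(sweep(rec, 2L, mu, `+`)))
    }
    # response carries no usable signal here: fall through to PCA
  }
  sv <- svd(Xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  rec <- sv$u %*% (d * t(sv$v))
  t(sweep(rec, 2L, mu, `+`))
}
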