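#' Build subtype centroids from labelled training samples
#'
#' A centroid is the per-gene arithmetic mean of expression over the samples
#' of one subtype.
#'
#' @param x an [expression_matrix()].
#' @param labels subtype label per sample (values from [SUBTYPES]).
#' @return A `centroid_set`: `subtype_names`, `gene_ids`, `centroids`
#'   (subtype x gene matrix).
#' @export
build_centroids <- function(x, labels) {
  stopifnot(inherits(x, "expression_matrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(x$values))
    stop("labels length != sample count")
  subtypes <- intersect(SUBTYPES, unique(labels))
  if (length(subtypes) == 0) subtypes <- unique(labels)
  empty <- setdiff(subtypes, labels)
  if (length(empty) > 0)
    stop("subtype(s) with zero samples: ", paste(empty, collapse = ", "))
  centroids <- t(vapply(subtypes, function(s)
    rowMeans(x$values[, labels == s, drop = FALSE]),
    numeric(nrow(x$values))))
  dimnames(centroids) <- list(subtypes, x$gene_ids)
  structure(list(subtype_names = subtypes, gene_ids = x$gene_ids,
                 centroids = centroids),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set: %d subtypes x %d genes\n",
              length(x$subtype_names), length(x$gene_ids)))
  invisible(x)
}

#' Nearest-centroid single sample prediction (SSP)
#'
#' Computes Spearman's rank correlation (midrank ties) between one sample
#' and each subtype centroid; the sample is assigned to the subtype with the
#' highest correlation, or designated Unclassified when every correlation
#' falls below `rho_threshold` (assignment requires max rho >= threshold).
#'
#' @param sample_vector numeric vector aligned to `centroids$gene_ids`
#'   (or named by gene, in which case it is aligned automatically).
#' @param centroids a `centroid_set`.
#' @param rho_threshold minimum correlation for assignment (default 0.1).
#' @return List: `label` (subtype or Unclassified), `rho` (named vector of
#'   the correlations).
#' @export
ssp_assign <- function(sample_vector, centroids, rho_threshold = 0.1) {
  stopifnot(inherits(centroids, "centroid_set"))
  if (!is.null(names(sample_vector)))
    sample_vector <- sample_vector[centroids$gene_ids]
  if (length(sample_vector) != length(centroids$gene_ids))
    stop("sample vector length != centroid gene count")
  if (length(sample_vector) < 3)
    stop("need at least 3 genes for rank correlation")
  if (stats::sd(sample_vector, na.rm = TRUE) == 0 ||
      anyNA(sample_vector)) {
    warning("constant or incomplete sample vector: correlations undefined")
    rho <- stats::setNames(rep(NA_real_, length(centroids$subtype_names)),
                           centroids$subtype_names)
    return(list(label = UNCLASSIFIED, rho = rho))
  }
  rho <- apply(centroids$centroids, 1L, function(cen)
    stats::cor(sample_vector, cen, method = "spearman"))
  top <- which(rho == max(rho))
  if (length(top) > 1L)
    warning("tied centroid correlations; keeping canonical order winner")
  label <- if (max(rho) >= rho_threshold)
    centroids$subtype_names[top[1L]] else UNCLASSIFIED
  list(label = label, rho = rho)
}

#' SSP over a whole cohort
#'
#' @param x an [expression_matrix()] whose genes cover the centroid panel.
#' @param centroids a `centroid_set`.
#' @param rho_threshold passed to [ssp_assign()].
#' @return Data frame: sample, one correlation column per subtype, label.
#' @export
ssp_classify <- function(x, centroids, rho_threshold = 0.1) {
  stopifnot(inherits(x, "expression_matrix"))
  sub <- subset_genes(x, centroids$gene_ids)
  res <- lapply(seq_len(ncol(sub$values)), function(j)
    ssp_assign(sub$values[, j], centroids, rho_threshold))
  rho <- do.call(rbind, lapply(res, `[[`, "rho"))
  data.frame(sample = x$sample_ids, rho,
             label = vapply(res, `[[`, "", "label"),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write centroid tables
#'
#' TSV layout: first column gene symbol, one column per subtype.
#'
#' @param path file path.
#' @return `read_centroids`: a `centroid_set`.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(m) <- "double"
  colnames(m) <- genes
  structure(list(subtype_names = rownames(m), gene_ids = genes,
                 centroids = m),
            class = "centroid_set")
}

#' @rdname read_centroids
#' @param centroids a `centroid_set` to write.
#' @export
write_centroids <- function(centroids, path) {
  stopifnot(inherits(centroids, "centroid_set"))
  df <- data.frame(gene = centroids$gene_ids, t(centroids$centroids),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
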