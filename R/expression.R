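#' Expression matrix container
#'
#' A light S3 wrapper around a numeric genes x samples matrix of log-scale
#' expression values.  Rows carry gene (or, pre-collapse, probeset)
#' identifiers; columns carry sample identifiers.  Missing values are allowed
#' until [impute_em()] has been run.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of row identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of column identifiers; defaults to
#'   `colnames(values)`.
#' @param probeset_ids optional character vector of platform probeset
#'   identifiers (kept alongside `gene_ids` before probeset collapsing).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              probeset_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (is.null(gene_ids))
    stop("gene_ids are required (rownames or explicit)")
  if (is.null(sample_ids))
    stop("sample_ids are required (colnames or explicit)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != row count (",
         nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != column count (",
         ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (!is.null(probeset_ids) && length(probeset_ids) != nrow(values))
    stop("probeset_ids length != row count")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         probeset_ids = probeset_ids),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$probeset_ids))
    cat("  probeset identifiers present (pre-collapse)\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0)
    cat(sprintf("  %d missing values (%.2f%%)\n", nmiss,
                100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects the dominant microarray layout: first column gene/probeset
#' identifier, header row of sample identifiers, one row per gene.  Empty
#' fields, `NA`, `NaN` and `null` are read as missing.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`
#'   (the matrix is transposed after reading).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, orientation = c("genes_in_rows",
                                                  "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "NaN", "null"))
  if (ncol(df) < 2)
    stop("expression file needs an ID column plus at least one sample: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @param id_column header for the identifier column.
#' @export
write_expression <- function(x, path, id_column = "gene") {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column probeset-to-gene map
#'
#' @param path TSV with columns `probeset` and `gene` (header optional when
#'   exactly two columns are present).
#' @return Named character vector mapping probeset -> gene symbol.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("probe map needs two columns: probeset, gene")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

# internal: subset an expression_matrix to a gene panel, preserving panel order
subset_genes <- function(x, genes) {
  missing <- setdiff(genes, x$gene_ids)
  if (length(missing) > 0)
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  idx <- match(genes, x$gene_ids)
  expression_matrix(x$values[idx, , drop = FALSE], gene_ids = genes,
                    sample_ids = x$sample_ids)
}
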