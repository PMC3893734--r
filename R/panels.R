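#' Packaged class-specific PAM50 gene panels
#'
#' Each intrinsic-subtype classifier uses 10 of the 50 PAM50 signature genes
#' (the class-specific panels originating from the ClaNC gene selection that
#' produced PAM50).  The panels ship with the published reference weight
#' vector of the first latent component of each one-versus-rest PLS fit,
#' stored verbatim.  Note the Luminal-B reference vector has squared norm
#' about 1.21 rather than 1 — it is kept exactly as published, not
#' renormalized.
#'
#' @return Named list of five `gene_panel` objects (`subtype_name`,
#'   `gene_ids`, `reference_weights`), in canonical subtype order.
#' @export
load_pam50_panels <- function() {
  path <- system.file("extdata", "pam50_panels.tsv", package = "plsSubtype",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  panels <- lapply(SUBTYPES, function(s) {
    rows <- df[df$subtype == s, ]
    gene_panel(s, rows$gene, rows$weight)
  })
  stats::setNames(panels, SUBTYPES)
}

#' Construct a gene panel
#'
#' @param subtype_name subtype the panel belongs to.
#' @param gene_ids ordered character vector of gene symbols (unique).
#' @param reference_weights optional signed reals, parallel to `gene_ids`.
#' @return A `gene_panel` object.
#' @export
gene_panel <- function(subtype_name, gene_ids, reference_weights = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("panel gene_ids must be unique")
  if (!is.null(reference_weights) &&
      length(reference_weights) != length(gene_ids))
    stop("reference_weights length != gene count")
  structure(list(subtype_name = subtype_name, gene_ids = gene_ids,
                 reference_weights = reference_weights),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s': %s\n", x$subtype_name,
              paste(x$gene_ids, collapse = ", ")))
  invisible(x)
}

#' Packaged published cross-tabulations
#'
#' Returns the two published SSP-versus-PLS confusion tables: the training
#' one (5 subtype rows x 5 subtypes + Unclassified columns, n = 139
#' prototype arrays) and the validation one (6 x 6 with Unclassified as the
#' last row and column, n = 535 independent arrays).
#'
#' @return List with elements `training` and `validation`, both
#'   `confusion_table` objects in canonical category order.
#' @export
load_printed_confusions <- function() {
  rd <- function(f) read_confusion(
    system.file("extdata", f, package = "plsSubtype", mustWork = TRUE))
  list(training = rd("table2_confusion.tsv"),
       validation = rd("table4_confusion.tsv"))
}
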