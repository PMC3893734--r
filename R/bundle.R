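#' Serialize a classifier bundle to a structured text file
#'
#' Writes the five fitted one-versus-rest classifiers — gene panels,
#' centring/scaling vectors, PLS weights/loadings/rotation, logistic
#' coefficients and thresholds — to a single JSON file.  Reloading the file
#' reproduces predicted probabilities to full double precision.
#'
#' @param classifiers named list of `subtype_classifier` objects.
#' @param path output file.
#' @export
save_bundle <- function(classifiers, path) {
  enc <- lapply(classifiers, function(clf) {
    list(subtype_name = clf$subtype_name,
         panel = clf$panel,
         gene_means = as.list(clf$gene_means),
         gene_sds = as.list(clf$gene_sds),
         center_only = clf$center_only,
         threshold = clf$threshold,
         k = clf$pls$k,
         gene_order = clf$pls$gene_order,
         W = clf$pls$W, P = clf$pls$P, C = clf$pls$C, R = clf$pls$R,
         x_var_explained = clf$pls$x_var_explained,
         y_var_explained = clf$pls$y_var_explained,
         beta0 = clf$lr$beta0, betas = clf$lr$betas)
  })
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a classifier bundle written by [save_bundle()]
#'
#' @param path JSON bundle file.
#' @return Named list of `subtype_classifier` objects (prediction-ready;
#'   training scores and cross-validation records are not stored).
#' @export
load_bundle <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  classifiers <- lapply(enc, function(e) {
    k <- as.integer(e$k)
    as_mat <- function(m) matrix(as.numeric(unlist(m)), ncol = k)
    pls <- structure(
      list(k = k, W = as_mat(e$W), P = as_mat(e$P),
           C = as.numeric(e$C), R = as_mat(e$R),
           x_var_explained = as.numeric(e$x_var_explained),
           y_var_explained = as.numeric(e$y_var_explained),
           x_cum_var = cumsum(as.numeric(e$x_var_explained)),
           y_cum_var = cumsum(as.numeric(e$y_var_explained)),
           gene_order = e$gene_order),
      class = "pls_model")
    structure(
      list(subtype_name = e$subtype_name, panel = e$panel,
           gene_means = unlist(e$gene_means),
           gene_sds = unlist(e$gene_sds),
           center_only = isTRUE(e$center_only),
           pls = pls,
           lr = list(beta0 = as.numeric(e$beta0),
                     betas = as.numeric(e$betas)),
           threshold = as.numeric(e$threshold)),
      class = "subtype_classifier")
  })
  stats::setNames(classifiers,
                  vapply(classifiers, `[[`, "", "subtype_name"))
}
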