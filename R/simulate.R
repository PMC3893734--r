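#' Specification of a synthetic expression cohort
#'
#' Describes the generative model the classifier assumes: each subtype's own
#' panel genes are shifted upward by `effect_size` (in units of the noise
#' standard deviation) for samples of that subtype, optional `cross_effects`
#' shift other subtypes' panels, background genes carry no signal, and
#' independent Gaussian noise is added to every cell.  A fraction of entries
#' can be masked as missing.  Values are on the log scale used throughout.
#'
#' @param n_per_subtype samples per subtype (scalar or length-5 vector).
#' @param panels named list of five `gene_panel` objects; default the
#'   packaged PAM50 panels.
#' @param background_genes count of extra no-signal genes (named BG0001...).
#' @param effect_size mean shift on a subtype's own panel genes, in noise-sd
#'   units.
#' @param cross_effects optional subtype x panel numeric matrix of shifts
#'   applied to other panels (rows: sample subtype; columns: panel).
#' @param noise_sd per-gene Gaussian noise standard deviation.
#' @param missing_rate fraction of cells masked missing, in \[0, 1).
#' @param seed integer seed (mandatory: cohorts are reproducible by design).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_per_subtype = 40, panels = load_pam50_panels(),
                            background_genes = 0, effect_size = 2,
                            cross_effects = NULL, noise_sd = 1,
                            missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (length(n_per_subtype) == 1L)
    n_per_subtype <- rep(n_per_subtype, length(panels))
  if (length(n_per_subtype) != length(panels))
    stop("n_per_subtype must be scalar or one per panel")
  structure(list(n_per_subtype = n_per_subtype, panels = panels,
                 background_genes = background_genes,
                 effect_size = effect_size, cross_effects = cross_effects,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic expression cohort
#'
#' Gene g of sample s takes the value shift(subtype(s), g) + N(0, noise_sd):
#' the shift is `effect_size` when g belongs to the sample's own subtype
#' panel, the corresponding `cross_effects` entry when g belongs to another
#' panel, and 0 for background genes.  Duplicate genes across panels are
#' allowed (shifts accumulate).  With the same seed the output is
#' bitwise identical.
#'
#' @param spec a [simulation_spec()].
#' @return List: `matrix` (an [expression_matrix()], genes x samples) and
#'   `labels` (true subtype per sample, canonical names).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  subtype_names <- names(spec$panels)
  panel_genes <- lapply(spec$panels, `[[`, "gene_ids")
  genes <- unique(unlist(panel_genes))
  if (spec$background_genes > 0)
    genes <- c(genes, sprintf("BG%04d", seq_len(spec$background_genes)))
  n <- sum(spec$n_per_subtype)
  labels <- rep(subtype_names, times = spec$n_per_subtype)
  sample_ids <- sprintf("S%04d", seq_len(n))

  shift <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
  for (si in seq_along(subtype_names)) {
    cols <- labels == subtype_names[si]
    shift[panel_genes[[si]], cols] <-
      shift[panel_genes[[si]], cols] + spec$effect_size
    if (!is.null(spec$cross_effects)) {
      for (pj in seq_along(subtype_names)) {
        if (pj == si) next
        ce <- spec$cross_effects[si, pj]
        if (!is.na(ce) && ce != 0)
          shift[panel_genes[[pj]], cols] <- shift[panel_genes[[pj]], cols] + ce
      }
    }
  }

  vals <- with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(length(genes) * n, sd = spec$noise_sd),
                    length(genes), n)
    v <- shift + noise
    if (spec$missing_rate > 0) {
      mask <- stats::runif(length(v)) < spec$missing_rate
      # keep at least one observed value per gene so imputation stays defined
      for (i in which(rowSums(matrix(!mask, nrow(v), n)) == 0))
        mask[(sample.int(n, 1) - 1) * nrow(v) + i] <- FALSE
      v[mask] <- NA_real_
    }
    v
  })
  dimnames(vals) <- list(genes, sample_ids)
  list(matrix = expression_matrix(vals), labels = labels)
}

#' Fit the full five-classifier pipeline on a labelled cohort
#'
#' Convenience wrapper used by the command-line `train` step and the
#' simulation studies: one one-versus-rest classifier per subtype, sharing a
#' configuration.
#'
#' @param x an [expression_matrix()].
#' @param labels subtype label per sample.
#' @param panels named list of `gene_panel`s (default packaged PAM50 panels).
#' @param k component count or `"auto"`.
#' @param ... passed to [fit_classifier()].
#' @return Named list of five `subtype_classifier` objects.
#' @export
fit_all_classifiers <- function(x, labels, panels = load_pam50_panels(),
                                k = "auto", ...) {
  stats::setNames(lapply(names(panels), function(s)
    fit_classifier(x, as.numeric(labels == s), panels[[s]], k = k,
                   subtype_name = s, ...)),
    names(panels))
}
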