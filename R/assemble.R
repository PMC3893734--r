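#' Combine five one-versus-rest probabilities into a single subtype call
#'
#' Standard mode: a sample is called into the subtype with the highest
#' probability provided that probability exceeds the threshold; it is flagged
#' ambiguous when two or more probabilities exceed the threshold; it is
#' Unclassified when none does.  Forced mode: the sample is always assigned
#' to the argmax subtype unless even the maximum probability fails to exceed
#' `forced_threshold` (default 0.1).  Exact argmax ties are broken by
#' canonical subtype order and flagged ambiguous.
#'
#' @param probabilities named numeric vector: one probability in (0, 1) per
#'   subtype in [SUBTYPES].
#' @param threshold positive-call threshold, strict inequality (default 0.5).
#' @param mode `"standard"` or `"forced"`.
#' @param forced_threshold minimum argmax probability for a forced call.
#' @return A `subtype_call` list: `probabilities`, `label`, `ambiguous`,
#'   `mode`.
#' @export
assemble_call <- function(probabilities, threshold = 0.5,
                          mode = c("standard", "forced"),
                          forced_threshold = 0.1) {
  mode <- match.arg(mode)
  missing <- setdiff(SUBTYPES, names(probabilities))
  if (length(missing) > 0)
    stop("missing subtype probabilities: ", paste(missing, collapse = ", "))
  p <- probabilities[SUBTYPES]
  if (any(p <= 0 | p >= 1))
    stop("probabilities must lie strictly in (0, 1)")

  top <- which(p == max(p))
  winner <- SUBTYPES[top[1L]]                 # canonical-order tie-break
  exceeds <- sum(p > threshold)
  if (mode == "standard") {
    label <- if (exceeds == 0L) UNCLASSIFIED else winner
    ambiguous <- exceeds >= 2L || (exceeds >= 1L && length(top) > 1L)
  } else {
    label <- if (max(p) > forced_threshold) winner else UNCLASSIFIED
    ambiguous <- length(top) > 1L && label != UNCLASSIFIED
  }
  structure(list(probabilities = p, label = label, ambiguous = ambiguous,
                 mode = mode),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("subtype_call: %s%s (%s mode)\n", x$label,
              if (x$ambiguous) " [ambiguous]" else "", x$mode))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Classify a cohort with five one-versus-rest classifiers
#'
#' Computes per-subtype probabilities — leave-one-out cross-validated ones
#' on a training cohort, plain model predictions on an external cohort —
#' and assembles one subtype call per sample.
#'
#' @param x an [expression_matrix()].
#' @param classifiers named list of five `subtype_classifier` objects, one
#'   per subtype in [SUBTYPES].
#' @param use_loocv use leave-one-out cross-validated probabilities (training
#'   cohort); requires `labels_list`.
#' @param labels_list named list of binary label vectors (one per subtype)
#'   used to refit during LOOCV; only with `use_loocv = TRUE`.
#' @param mode,threshold,forced_threshold passed to [assemble_call()].
#' @return A `cohort_calls` object: data frame `calls` (sample, five
#'   probability columns, label, ambiguous), plus summary counts
#'   `n_unclassified`, `n_ambiguous`.
#' @export
classify_cohort <- function(x, classifiers, use_loocv = FALSE,
                            labels_list = NULL,
                            mode = c("standard", "forced"), threshold = 0.5,
                            forced_threshold = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expression_matrix"))
  missing <- setdiff(SUBTYPES, names(classifiers))
  if (length(missing) > 0)
    stop("classifier list lacks subtypes: ", paste(missing, collapse = ", "))

  prob <- sapply(SUBTYPES, function(s) {
    clf <- classifiers[[s]]
    if (use_loocv) {
      if (is.null(labels_list[[s]]))
        stop("use_loocv = TRUE requires labels_list entries for every subtype")
      loocv_probabilities(x, labels_list[[s]], clf$panel, k = clf$pls$k,
                          subtype_name = s, center_only = clf$center_only)
    } else {
      predict_probability(clf, x)
    }
  })
  prob <- matrix(prob, ncol = length(SUBTYPES),
                 dimnames = list(x$sample_ids, SUBTYPES))

  calls <- lapply(seq_len(nrow(prob)), function(i)
    assemble_call(prob[i, ], threshold = threshold, mode = mode,
                  forced_threshold = forced_threshold))
  df <- data.frame(sample = x$sample_ids, prob,
                   label = vapply(calls, `[[`, "", "label"),
                   ambiguous = vapply(calls, `[[`, NA, "ambiguous"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(calls = df, mode = mode,
                 n_unclassified = sum(df$label == UNCLASSIFIED),
                 n_ambiguous = sum(df$ambiguous)),
            class = "cohort_calls")
}

#' @export
print.cohort_calls <- function(x, ...) {
  cat(sprintf("cohort_calls (%s mode): %d samples, %d unclassified, %d ambiguous\n",
              x$mode, nrow(x$calls), x$n_unclassified, x$n_ambiguous))
  print(table(x$calls$label))
  invisible(x)
}

#' Write cohort calls as TSV
#'
#' Columns: sample, the five subtype probabilities, label, ambiguous flag.
#' Summary counts are appended as `#`-prefixed comment lines.
#'
#' @param calls a `cohort_calls` object.
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "cohort_calls"))
  utils::write.table(calls$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# mode\t%s\n# n_unclassified\t%d\n# n_ambiguous\t%d\n",
              calls$mode, calls$n_unclassified, calls$n_ambiguous),
      file = path, append = TRUE)
  invisible(path)
}

#' Read cohort calls written by [write_calls()]
#'
#' @param path TSV file.
#' @return Data frame of calls (comment lines dropped).
#' @export
read_calls <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
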