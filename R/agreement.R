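#' Cross-tabulate two call sets
#'
#' Builds a square confusion table over a fixed category order, optionally
#' dropping rows/columns for selected labels (typically Unclassified).
#'
#' @param calls_a,calls_b named character vectors of labels (names = sample
#'   identifiers) or plain vectors of equal length over the same samples.
#' @param label_order character vector fixing row/column order.
#' @param drop_labels labels whose rows and columns are removed after
#'   tabulation.
#' @return A `confusion_table`: `row_labels`, `col_labels`, `counts`.
#' @export
cross_tabulate <- function(calls_a, calls_b,
                           label_order = c(SUBTYPES, UNCLASSIFIED),
                           drop_labels = NULL) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    only_a <- setdiff(names(calls_a), names(calls_b))
    only_b <- setdiff(names(calls_b), names(calls_a))
    if (length(only_a) > 0 || length(only_b) > 0)
      stop("samples present in one call set only: ",
           paste(utils::head(c(only_a, only_b), 5), collapse = ", "))
    calls_b <- calls_b[names(calls_a)]
  } else if (length(calls_a) != length(calls_b)) {
    stop("unnamed call sets must have equal length")
  }
  seen <- unique(c(calls_a, calls_b))
  unknown <- setdiff(seen, label_order)
  if (length(unknown) > 0)
    stop("labels outside label_order: ", paste(unknown, collapse = ", "))
  counts <- table(factor(calls_a, levels = label_order),
                  factor(calls_b, levels = label_order))
  counts <- matrix(as.integer(counts), nrow = length(label_order),
                   dimnames = list(label_order, label_order))
  confusion_table(counts, drop_labels = drop_labels)
}

#' Construct a confusion table from a count matrix
#'
#' @param counts non-negative integer matrix with row/column names.
#' @param row_labels,col_labels optional explicit orders.
#' @param drop_labels labels whose rows and columns are removed.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(counts, row_labels = rownames(counts),
                            col_labels = colnames(counts),
                            drop_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(row_labels, col_labels)
  if (!is.null(drop_labels)) {
    keep_r <- !(row_labels %in% drop_labels)
    keep_c <- !(col_labels %in% drop_labels)
    counts <- counts[keep_r, keep_c, drop = FALSE]
    row_labels <- row_labels[keep_r]
    col_labels <- col_labels[keep_c]
  }
  structure(list(row_labels = row_labels, col_labels = col_labels,
                 counts = counts),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion_table: %d x %d, n = %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement with partial credit for near-diagonal
#' disagreement.  Linear (Cicchetti-Allison) weights are
#' `w_ij = 1 - |i - j| / (R - 1)`; quadratic weights square the distance
#' term; unweighted kappa uses the identity weight.  The standard error is
#' the Fleiss-Cohen-Everitt large-sample formula and the 95% confidence
#' interval `kappa +/- 1.96 SE`, truncated to `[-1, 1]`.
#'
#' @param table a square `confusion_table` with identically ordered
#'   categories on both axes.
#' @param scheme `"linear"`, `"quadratic"` or `"unweighted"`.
#' @return A `kappa_result`: `kappa`, `se`, `ci_low`, `ci_high`,
#'   `weight_scheme`, `n`.
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic",
                                             "unweighted")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "confusion_table"))
  m <- table$counts
  if (nrow(m) != ncol(m))
    stop("kappa needs a square table (", nrow(m), " x ", ncol(m), ")")
  if (!identical(table$row_labels, table$col_labels))
    warning("row and column category orders differ; positions are matched")
  n <- sum(m)
  if (n <= 0) stop("empty confusion table")
  R <- nrow(m)
  d <- abs(outer(seq_len(R), seq_len(R), `-`))
  w <- switch(scheme,
              linear = if (R == 1) diag(1) else 1 - d / (R - 1),
              quadratic = if (R == 1) diag(1) else 1 - (d / (R - 1))^2,
              unweighted = (d == 0) * 1)
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (abs(1 - pe) < 1e-12)
    stop("degenerate marginals: expected agreement is 1, kappa undefined")
  kappa <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt asymptotic variance of the weighted kappa estimate
  wr <- drop(w %*% pc)                        # row-wise expected weights
  wc <- drop(pr %*% w)                        # column-wise expected weights
  term <- outer(wr, wc, `+`)
  inner <- sum(p * (w * (1 - pe) - term * (1 - po))^2)
  var_k <- (inner - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  structure(list(kappa = kappa, se = se,
                 ci_low = max(kappa - 1.96 * se, -1),
                 ci_high = min(kappa + 1.96 * se, 1),
                 weight_scheme = scheme, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("weighted kappa (%s): %.3f (95%% CI %.3f-%.3f, SE %.4f, n = %d)\n",
              x$weight_scheme, x$kappa, x$ci_low, x$ci_high, x$se, x$n))
  invisible(x)
}

#' Read / write confusion tables as TSV
#'
#' Layout: first column row label, header of column labels.
#'
#' @param path file path.
#' @param drop_labels optional labels to drop after reading.
#' @return `read_confusion`: a `confusion_table`.
#' @export
read_confusion <- function(path, drop_labels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rl <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- rl
  confusion_table(m, drop_labels = drop_labels)
}

#' @rdname read_confusion
#' @param table a `confusion_table` to write.
#' @export
write_confusion <- function(table, path) {
  stopifnot(inherits(table, "confusion_table"))
  df <- data.frame(label = table$row_labels, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
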