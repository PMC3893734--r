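test_that("separable clusters give perfect training accuracy", {
  d <- two_cluster_cohort(shift = 3, seed = 4)
  clf <- suppressMessages(
    fit_classifier(d$x, d$y, d$panel, k = 1, subtype_name = "pos"))
  pr <- predict_probability(clf, d$x)
  expect_equal(unname(as.numeric(pr > 0.5)), d$y)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("k = 1 probabilities match an independent PLS + IRLS composition", {
  # mild overlap so plain IRLS converges without the ridge fallback
  d <- two_cluster_cohort(n_pos = 15, n_neg = 15, shift = 1, seed = 6)
  clf <- fit_classifier(d$x, d$y, d$panel, k = 1)
  # oracle: standardize, project on normalized X0'Y0, standard glm IRLS
  v <- d$x$values
  v <- (v - rowMeans(v)) / apply(v, 1, sd)
  X0 <- t(v)
  y0 <- drop(scale(d$y))
  w <- drop(crossprod(X0, y0)); w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  score <- drop(X0 %*% w)
  or <- glm(d$y ~ score, family = binomial())
  expect_equal(unname(predict_probability(clf, d$x)),
               unname(fitted(or)), tolerance = 1e-6)
})

test_that("probabilities are the logistic closed form of the scores", {
  # hand-built classifier: identity-like PLS on one gene, known coefficients
  pls <- structure(list(k = 1L, W = matrix(1), P = matrix(1), C = 1,
                        R = matrix(1), x_var_explained = 1,
                        y_var_explained = 1, x_cum_var = 1, y_cum_var = 1,
                        gene_order = "G01"),
                   class = "pls_model")
  clf <- structure(list(subtype_name = "t", panel = "G01",
                        gene_means = c(G01 = 0), gene_sds = c(G01 = 1),
                        center_only = FALSE, pls = pls,
                        lr = list(beta0 = 0, betas = 1), threshold = 0.5),
                   class = "subtype_classifier")
  x <- make_expr(matrix(c(0, log(3), -20), 1, 3), genes = "G01")
  # standardization is frozen to mean 0 / sd 1, so scores equal raw values
  pr <- unname(predict_probability(clf, x))
  expect_equal(pr[1], 0.5)            # linear predictor 0
  expect_equal(pr[2], 0.75)           # linear predictor ln 3
  expect_lt(pr[3], 1e-8)              # saturated tail stays inside (0, 1)
  expect_gt(pr[3], 0)
  # monotone in the linear predictor
  xs <- make_expr(matrix(seq(-3, 3, length.out = 13), 1), genes = "G01")
  expect_true(all(diff(predict_probability(clf, xs)) > 0))
})

test_that("classifier guards: class sizes, binary labels, panel coverage", {
  d <- two_cluster_cohort(n_pos = 2, n_neg = 10, seed = 5)
  expect_error(fit_classifier(d$x, d$y, d$panel, k = 1), "fewer than 3")
  d2 <- two_cluster_cohort(seed = 5)
  expect_error(fit_classifier(d2$x, d2$y + 1, d2$panel, k = 1), "binary")
  expect_error(fit_classifier(d2$x, d2$y, c(d2$panel, "MISSING"), k = 1),
               "MISSING")
  clf <- suppressMessages(fit_classifier(d2$x, d2$y, d2$panel, k = 1))
  expect_error(predict_probability(clf, make_expr(matrix(0, 1, 1))), "absent")
})

test_that("LOOCV matches a hand-rolled per-sample refit loop", {
  d <- two_cluster_cohort(n_pos = 4, n_neg = 4, p = 4, shift = 1.5, seed = 9)
  pr <- suppressMessages(
    loocv_probabilities(d$x, d$y, d$panel, k = 1))
  manual <- sapply(seq_along(d$y), function(i) {
    tr <- expression_matrix(d$x$values[, -i, drop = FALSE],
                            gene_ids = d$x$gene_ids,
                            sample_ids = d$x$sample_ids[-i])
    clf <- suppressMessages(fit_classifier(tr, d$y[-i], d$panel, k = 1))
    ho <- expression_matrix(d$x$values[, i, drop = FALSE],
                            gene_ids = d$x$gene_ids,
                            sample_ids = d$x$sample_ids[i])
    predict_probability(clf, ho)
  })
  expect_equal(unname(pr), unname(manual), tolerance = 1e-8)
  # separable clusters: every held-out probability on the correct side
  d6 <- two_cluster_cohort(n_pos = 3, n_neg = 3, shift = 4, seed = 10)
  pr6 <- suppressMessages(loocv_probabilities(d6$x, d6$y, d6$panel, k = 1))
  expect_equal(unname(as.numeric(pr6 > 0.5)), d6$y)
})

test_that("LOOCV never uses the held-out row", {
  d <- two_cluster_cohort(n_pos = 6, n_neg = 6, shift = 1.2, seed = 11)
  pr <- suppressMessages(loocv_probabilities(d$x, d$y, d$panel, k = 1))
  # duplicate sample 1 with flipped label; its held-out probability must move
  x2 <- expression_matrix(cbind(d$x$values, d$x$values[, 1]),
                          gene_ids = d$x$gene_ids,
                          sample_ids = c(d$x$sample_ids, "DUP"))
  y2 <- c(d$y, 1 - d$y[1])
  pr2 <- suppressMessages(loocv_probabilities(x2, y2, d$panel, k = 1))
  expect_gt(abs(pr2[1] - pr[1]), 1e-6)
  # degenerate class sizes are rejected before the loop starts
  expect_error(
    suppressMessages(loocv_probabilities(
      d$x, c(1, rep(0, 11)), d$panel, k = 1)),
    "fewer than 3")
})

test_that("classifier metrics match their definitions", {
  m <- classifier_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # all-tied probabilities: AUC 0.5 by midranks
  expect_equal(classifier_metrics(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # midrank AUC equals the brute-force count over positive-negative pairs
  p <- c(0.6, 0.4, 0.7, 0.2); y <- c(1, 0, 0, 1)
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  brute <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                       ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  expect_equal(classifier_metrics(p, y)$auc, brute)
  expect_equal(brute, 0.25)
  # ... and with ties present
  pt <- c(0.6, 0.6, 0.3, 0.2); yt <- c(1, 0, 1, 0)
  pairs <- expand.grid(i = which(yt == 1), j = which(yt == 0))
  brute_t <- mean(ifelse(pt[pairs$i] > pt[pairs$j], 1,
                         ifelse(pt[pairs$i] == pt[pairs$j], 0.5, 0)))
  expect_equal(classifier_metrics(pt, yt)$auc, brute_t)
  # accuracy identity: acc = (sens*P + spec*N) / (P + N)
  set.seed(12)
  p2 <- runif(40); y2 <- rbinom(40, 1, 0.4)
  m2 <- classifier_metrics(p2, y2)
  P <- sum(y2); N <- sum(1 - y2)
  expect_equal(m2$accuracy, (m2$sensitivity * P + m2$specificity * N) / (P + N))
  expect_true(m2$adjusted_r2 <= 1)
  # single-class labels: AUC undefined
  expect_true(is.na(classifier_metrics(c(0.2, 0.8), c(1, 1))$auc))
})

test_that("LOOCV AUC does not exceed resubstitution AUC on average", {
  set.seed(30)
  diff_sum <- 0
  for (r in 1:10) {
    d <- two_cluster_cohort(n_pos = 8, n_neg = 8, p = 4, shift = 0.8,
                            seed = 100 + r)
    clf <- suppressMessages(fit_classifier(d$x, d$y, d$panel, k = 1))
    full <- classifier_metrics(predict_probability(clf, d$x), d$y)$auc
    cvp <- suppressMessages(loocv_probabilities(d$x, d$y, d$panel, k = 1))
    cv <- classifier_metrics(cvp, d$y)$auc
    diff_sum <- diff_sum + (full - cv)
  }
  expect_gte(diff_sum / 10, 0)
})

test_that("auto component selection lands in the expected range", {
  coh <- generate_cohort(simulation_spec(n_per_subtype = 12, seed = 77))
  clf <- suppressMessages(
    fit_classifier(coh$matrix, as.numeric(coh$labels == "Basal-like"),
                   load_pam50_panels()[["Basal-like"]], k = "auto",
                   seed = 77))
  expect_true(clf$pls$k %in% 1:3)
  expect_s3_class(clf$cv, "cv_result")
  expect_lte(clf$cv$k_selected, clf$cv$k_min_press)
})
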