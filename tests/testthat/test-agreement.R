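test_that("kappa reproduces hand-evaluated confusion matrices", {
  # worked 2x2 example: P0 = 35/50, Pe = (25*30 + 25*20)/50^2
  m <- confusion_matrix(matrix(c(20, 10, 5, 15), 2))
  k <- cohens_kappa(m)
  expect_equal(k$P0, 0.70)
  expect_equal(k$Pe, 0.50)
  expect_equal(k$kappa, 0.40)
  expect_equal(consistency_rate(m), 0.70)
  # perfect agreement on any diagonal matrix
  d <- confusion_matrix(diag(c(17, 4, 29)))
  expect_equal(cohens_kappa(d)$kappa, 1)
  expect_equal(consistency_rate(d), 1)
  # total disagreement
  anti <- confusion_matrix(matrix(c(0, 10, 10, 0), 2))
  expect_equal(consistency_rate(anti), 0)
  expect_lt(cohens_kappa(anti)$kappa, 0)
})

test_that("kappa is invariant under simultaneous class permutation", {
  set.seed(21)
  m <- matrix(rpois(9, 20), 3)
  p <- sample(3)
  expect_equal(cohens_kappa(confusion_matrix(m))$kappa,
               cohens_kappa(confusion_matrix(m[p, p]))$kappa)
})

test_that("degenerate agreement tables are flagged", {
  expect_error(cohens_kappa(confusion_matrix(matrix(c(10, 0, 0, 0), 2))),
               "undefined")
  expect_error(confusion_matrix(matrix(0, 2, 2)), "observations")
})

test_that("independent raters with fixed marginals give kappa near zero", {
  set.seed(8)
  n <- 20000
  r1 <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  r2 <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  k <- cohens_kappa(confusion_matrix(r1, r2))
  expect_lt(abs(k$kappa), 0.02)
})

test_that("confusion matrices cross-tabulate call vectors", {
  m <- confusion_matrix(c("x", "x", "y"), c("x", "y", "y"))
  expect_equal(sum(m), 3)
  expect_equal(unname(diag(unclass(m))), c(1, 1))
})

test_that("multi-label determinations reduce by the priority rule", {
  calls <- list(c("healthy", "nonepithelial"),
                c("nonepithelial"),
                c("healthy", "cancerous"),
                c("cancerous"))
  expect_equal(reduce_determinations(calls),
               c("healthy", "nonepithelial", "cancerous", "cancerous"))
  expect_equal(reduce_determinations(list(c("healthy", "cancerous")),
                                     priority = c("healthy", "cancerous",
                                                  "nonepithelial")),
               "healthy")
})

test_that("binary metrics match the defining ratios and flag undefined", {
  bm <- binary_metrics(30, 10, 50, 10)
  expect_equal(bm$accuracy, 0.80)
  expect_equal(bm$precision, 0.75)
  expect_equal(bm$recall, 0.75)
  expect_equal(bm$f1, 0.75)
  expect_length(bm$undefined, 0)
  perfect <- binary_metrics(5, 0, 5, 0)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), rep(1, 4))
  miss <- binary_metrics(0, 5, 5, 10)
  expect_equal(miss$recall, 0)
  expect_equal(miss$f1, 0)
  nopos <- binary_metrics(0, 0, 5, 5)
  expect_true(is.na(nopos$precision))
  expect_true("precision" %in% nopos$undefined)
})

test_that("accuracy is the prevalence-weighted mix of recall and specificity", {
  set.seed(31)
  for (i in 1:20) {
    cts <- rpois(4, 20) + 1
    bm <- binary_metrics(cts[1], cts[2], cts[3], cts[4])
    P <- cts[1] + cts[4]; N <- cts[2] + cts[3]
    spec <- cts[3] / N
    expect_equal(bm$accuracy,
                 (P * bm$recall + N * spec) / (P + N), tolerance = 1e-12)
  }
})

test_that("ROC threshold sweep matches the exhaustive-threshold oracle", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    scores <- round(runif(n), 2)  # force ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    rc <- roc_curve(scores, pos)
    oracle <- brute_roc_points(scores, pos)
    expect_equal(cbind(rc$fpr, rc$tpr), unname(oracle))
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
  }
})

test_that("ROC handles perfect separation and constant scores", {
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(auc(rc), 1)
  flat <- roc_curve(rep(0.7, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(cbind(flat$fpr, flat$tpr),
               cbind(c(0, 1), c(0, 1)))
  expect_equal(auc(flat), 0.5)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals the Mann-Whitney pairwise statistic", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    scores <- sample(round(runif(n), 1))  # heavy ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(auc(roc_curve(scores, pos)), brute_auc(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under label swap with score negation", {
  set.seed(29)
  scores <- rnorm(50)
  pos <- runif(50) < 0.5
  expect_equal(auc(roc_curve(scores, pos)),
               auc(roc_curve(-scores, !pos)), tolerance = 1e-12)
})

test_that("AUC agrees with pROC as an independent implementation", {
  set.seed(37)
  scores <- rnorm(80)
  pos <- runif(80) < 0.5
  got <- auc(roc_curve(scores, pos))
  want <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                         quiet = TRUE, direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("permutation null AUC sits at chance level", {
  set.seed(41)
  scores <- rnorm(200)
  pos <- runif(200) < 0.5
  expect_lt(abs(permutation_null_auc(scores, pos, n_perm = 50) - 0.5), 0.02)
})
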