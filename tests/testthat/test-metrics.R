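# Metric suite: one-vs-rest confusion counts, precision/recall/F1,
# micro averages, micro ROC-AUC against an exhaustive oracle, and
# Scott's Pi including ordinal weighting and degenerate inputs.

test_that("one-vs-rest confusion counts match hand tallies", {
  # four classes, one error: true moderate predicted none
  cc <- confusion_counts(c(1, 2, 3, 4), c(1, 2, 3, 1), K = 4)
  expect_equal(unname(cc[1, ]), c(1, 1, 0, 2))  # TP FP FN TN for 'none'
  expect_equal(unname(cc[4, ]), c(0, 0, 1, 3))  # 'moderate' missed
  expect_true(all(rowSums(cc) == 4))
  expect_equal(sum(cc[, "TP"]), 3)

  perfect <- confusion_counts(rep(1:4, 2), rep(1:4, 2), K = 4)
  expect_true(all(perfect[, c("FP", "FN")] == 0))

  single <- confusion_counts(3, 3, K = 4)
  expect_equal(unname(single[3, ]), c(1, 0, 0, 0))
  expect_equal(unname(single[-3, "TN"]), rep(1, 3))

  expect_error(confusion_counts(c(1, 2), 1, K = 2), class = "cf_validation_error")
  expect_error(confusion_counts(c(1, 5), c(1, 2), K = 4), class = "cf_validation_error")
})

test_that("per-class precision/recall/F1 evaluate the closed forms with a zero-denominator policy", {
  cc <- confusion_counts(c(1, 2, 3, 4), c(1, 2, 3, 1), K = 4)
  prf <- per_class_prf(cc)
  expect_equal(prf$precision[1], 0.5)
  expect_equal(prf$recall[1], 1.0)
  expect_equal(prf$f1[1], 2 / 3)
  # class never predicted: precision undefined, reported 0
  expect_false(prf$precision_defined[4])
  expect_equal(prf$precision[4], 0)
  # harmonic-mean identity: P == R == p gives F1 == p
  cc2 <- confusion_counts(c(1, 1, 2, 2), c(1, 2, 1, 2), K = 2)
  prf2 <- per_class_prf(cc2)
  expect_equal(prf2$f1, prf2$precision)
})

test_that("accuracy is the correct fraction", {
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 1)), 0.75)
  expect_equal(accuracy(1:4, 1:4), 1)
  expect_equal(accuracy(c(1, 1), c(2, 2)), 0)
  expect_error(accuracy(1:3, 1:2), class = "cf_validation_error")
})

test_that("micro averages pool counts and collapse to accuracy on single-label tasks", {
  cc <- confusion_counts(c(1, 2, 3, 4), c(1, 2, 3, 1), K = 4)
  mi <- micro_average(cc)
  expect_equal(mi$f1, 0.75)
  expect_equal(mi$precision, mi$recall)
  set.seed(101)
  for (trial in 1:50) {
    n <- sample(1:40, 1); K <- sample(2:5, 1)
    truth <- sample.int(K, n, replace = TRUE)
    pred <- sample.int(K, n, replace = TRUE)
    mi <- micro_average(confusion_counts(truth, pred, K))
    acc <- accuracy(truth, pred)
    expect_identical(mi$precision, mi$recall)
    expect_equal(mi$f1, acc)
  }
})

test_that("micro ROC-AUC handles the limiting cases and matches the pairwise oracle", {
  truth <- c(1, 1, 2)
  onehot <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(roc_auc_micro(truth, onehot), 1)
  expect_equal(roc_auc_micro(truth, matrix(0.5, 3, 2)), 0.5)
  expect_equal(roc_auc_micro(truth, rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))), 1)
  set.seed(77)
  for (trial in 1:30) {
    n <- sample(2:40, 1); K <- sample(2:5, 1)  # N*K stays <= 200
    truth <- sample.int(K, n, replace = TRUE)
    probs <- matrix(runif(n * K), n, K); probs <- probs / rowSums(probs)
    expect_equal(roc_auc_micro(truth, probs), micro_auc_oracle(truth, probs),
                 tolerance = 1e-12)
  }
})

test_that("binary column slices of the AUC agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  truth <- sample.int(4, 60, replace = TRUE)
  probs <- matrix(runif(240), 60, 4); probs <- probs / rowSums(probs)
  ours <- roc_auc_per_class(truth, probs)
  for (k in 1:4) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = as.integer(truth == k), predictor = probs[, k],
      direction = "<", quiet = TRUE)))
    expect_equal(ours[k], as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Scott's Pi matches the pooled-marginal hand example and its edge cases", {
  r <- scotts_pi(c(1, 1, 2, 2), c(1, 2, 2, 2), K = 2)
  expect_equal(r$po, 0.75)
  expect_equal(r$pe, 17 / 32)
  expect_equal(r$pi, 7 / 15)

  expect_equal(scotts_pi(c(1, 2, 1, 2), c(1, 2, 1, 2), K = 2)$pi, 1)

  degenerate <- scotts_pi(rep(1L, 5), rep(1L, 5), K = 3)
  expect_false(degenerate$defined)
  expect_true(is.na(degenerate$pi))
})

test_that("Scott's Pi is symmetric and reduces to Cohen's kappa on equal marginals", {
  set.seed(13)
  for (trial in 1:40) {
    n <- sample(4:60, 1); K <- sample(2:5, 1)
    a <- sample.int(K, n, replace = TRUE)
    b <- sample.int(K, n, replace = TRUE)
    f <- scotts_pi(a, b, K); g <- scotts_pi(b, a, K)
    expect_equal(f$po, g$po); expect_equal(f$pe, g$pe)
    if (f$defined) expect_equal(f$pi, g$pi)
    # a permutation of a has identical marginals: pi == kappa there
    bp <- sample(a)
    r <- scotts_pi(a, bp, K)
    if (r$defined)
      expect_equal(r$pi, cohen_kappa_oracle(a, bp, K), tolerance = 1e-12)
  }
})

test_that("ordinal weighting credits near-misses and keeps pi = 1 only for zero weighted disagreement", {
  a <- c(1, 2, 3, 4, 1, 2)
  b <- c(2, 3, 4, 3, 1, 2)  # all errors adjacent
  un <- scotts_pi(a, b, 4, "none")
  li <- scotts_pi(a, b, 4, "linear")
  qu <- scotts_pi(a, b, 4, "quadratic")
  expect_true(li$po > un$po)       # adjacent misses earn partial credit
  expect_true(qu$po > li$po)       # quadratic is gentler still
  expect_lt(abs(scotts_pi(a, a, 4, "linear")$pi - 1), 1e-12)
  expect_lt(li$pi, 1)
})

test_that("the assembled metrics report is internally consistent", {
  set.seed(21)
  ps <- random_pset(80, scheme4)
  rep <- metrics_report(ps$truth, ps$probs, scheme4)
  expect_equal(rep$micro$f1, rep$accuracy)
  expect_identical(rep$per_class$class, scheme4$names)
  expect_true(rep$roc_auc_micro >= 0 && rep$roc_auc_micro <= 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$accuracy, rep$accuracy)
  expect_equal(parsed$scotts_pi_vs_truth$pi, rep$scotts_pi_vs_truth$pi)
})

test_that("the pairwise agreement matrix matches direct Scott's Pi calls cell by cell", {
  set.seed(31)
  ids <- sprintf("s%02d", 1:40)
  truth <- sample.int(4, 40, replace = TRUE)
  models <- lapply(c("m1", "m2", "m3"), function(mid) {
    p <- matrix(runif(160), 40, 4); p <- p / rowSums(p)
    prediction_set(mid, ids, p, scheme4, truth = truth)
  })
  m <- agreement_matrix(models)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  labs <- lapply(models, function(x) argmax_labels(x$probs))
  for (i in 1:3) for (j in 1:3)
    expect_equal(m[i, j], scotts_pi(labs[[i]], labs[[j]], 4)$pi)
})
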