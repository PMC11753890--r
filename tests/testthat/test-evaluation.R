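test_that("confusion metrics match their closed forms", {
  perfect <- confusion_metrics(10, 10, 0, 0)
  expect_equal(perfect$Acc, 1)
  expect_equal(perfect$Sen, 1)
  expect_equal(perfect$Spe, 1)
  expect_equal(perfect$MCC, 1)

  m <- confusion_metrics(6, 4, 1, 1)
  expect_equal(m$MCC, 23 / 35)
  expect_equal(m$Acc, 10 / 12)
  expect_equal(m$Sen, 6 / 7)
  expect_equal(m$Spe, 4 / 5)

  degen <- confusion_metrics(0, 10, 0, 0)
  expect_equal(degen$MCC, 0)
  expect_true(degen$mcc_degenerate)
})

test_that("MCC is symmetric under class swap", {
  set.seed(5)
  for (i in 1:20) {
    cc <- sample(0:15, 4, replace = TRUE)
    a <- confusion_metrics(cc[1], cc[2], cc[3], cc[4])$MCC
    b <- confusion_metrics(cc[2], cc[1], cc[4], cc[3])$MCC
    expect_equal(a, b)
  }
})

test_that("AUC handles perfect ranking, ties, complements and the null", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), y), 1)
  expect_equal(roc_auc(rep(0.5, 4), y), 0.5)

  set.seed(3)
  for (i in 1:10) {
    s <- rnorm(30)
    yy <- rep(c(0, 1), 15)
    expect_equal(roc_auc(s, yy) + roc_auc(-s, yy), 1, tolerance = 1e-12)
  }

  aucs <- vapply(1:20, function(i) {
    set.seed(i)
    roc_auc(rnorm(100), rep(c(0, 1), 50))
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("rank-formula AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- rnorm(60)
  y <- rbinom(60, 1, 0.4)
  ours <- roc_auc(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("average precision steps over thresholds", {
  y <- c(0, 0, 1, 1)
  expect_equal(pr_auc(c(0.1, 0.2, 0.8, 0.9), y), 1)
  expect_equal(pr_auc(rep(0.3, 4), y), 0.5)  # all tied -> prevalence

  # hand-computed case: scores 4 > 3 > 2 > 1, labels 1 0 1 0
  # steps: k=1 P=1 R=.5; k=3 P=2/3 R=1 -> AP = .5*1 + .5*(2/3)
  expect_equal(pr_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.5 + 0.5 * 2 / 3)
})

test_that("stratified folds balance both classes and reproduce by seed", {
  y <- rep(c(1, 0), each = 10)
  f <- stratified_kfold(y, k = 5L, seed = 3L)
  for (k in 1:5) {
    expect_equal(sum(y[f == k] == 1), 2)
    expect_equal(sum(y[f == k] == 0), 2)
  }

  y2 <- c(rep(1, 11), rep(0, 9))
  f2 <- stratified_kfold(y2, k = 5L, seed = 3L)
  pos <- vapply(1:5, function(k) sum(y2[f2 == k] == 1), numeric(1))
  neg <- vapply(1:5, function(k) sum(y2[f2 == k] == 0), numeric(1))
  expect_true(all(pos %in% 2:3))
  expect_true(all(neg %in% 1:2))
  expect_equal(sum(pos), 11)
  expect_equal(sum(neg), 9)

  expect_identical(stratified_kfold(y, 5L, seed = 8L),
                   stratified_kfold(y, 5L, seed = 8L))
  expect_error(stratified_kfold(c(1, 1, 0, 0), k = 3L), ">= k")
})

test_that("cross-validated metrics agree with stored confusion recomputation", {
  ft <- gen_multiview_dataset(n = 40L, blocks = c(A = 10L),
                              informative = list(A = 1:4), shift = 3,
                              seed = 12)
  cv <- cross_validate(ft, ridge_train, ridge_predict, k = 5L, seed = 2L)
  expect_equal(nrow(cv$folds), 5L)
  expect_true(all(cv$folds$Acc >= 0 & cv$folds$Acc <= 1))
  expect_true(all(cv$folds$MCC >= -1 & cv$folds$MCC <= 1))
  # recompute one fold's confusion metrics from scratch
  f <- cv$assignment
  tr <- f != 1L
  model <- ridge_train(ft$matrix[tr, ], ft$labels[tr])
  sc <- ridge_predict(model, ft$matrix[!tr, ])
  cc <- confusion_counts(ft$labels[!tr], as.integer(sc > 0.5))
  m <- confusion_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
  expect_equal(cv$folds$Acc[1], m$Acc)
  expect_equal(cv$folds$MCC[1], m$MCC)
})
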