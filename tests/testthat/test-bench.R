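test_that("stratified split preserves class ratios and is seeded", {
  f <- random_feature_records(200)
  f$label <- rep(c(0L, 1L), each = 100)
  sp <- stratified_split(f, 0.25, seed = 1)
  expect_equal(sum(sp$test$label == 0), 25)
  expect_equal(sum(sp$test$label == 1), 25)
  expect_equal(nrow(sp$train) + nrow(sp$test), 200)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)

  sp2 <- stratified_split(f, 0.25, seed = 1)
  expect_identical(sp$test$sample_id, sp2$test$sample_id)

  f649 <- random_feature_records(649)
  f649$label <- rep(c(0L, 1L), c(211, 438))
  n_test <- nrow(stratified_split(f649, 0.25, seed = 0)$test)
  expect_true(n_test %in% c(162, 163))

  single <- f[f$label == 1, ]
  expect_error(stratified_split(single), "single class")
})

test_that("the metric chain reproduces the reference confusion-matrix results", {
  ref <- busi_reference_results()
  for (i in seq_len(nrow(ref))) {
    cm <- reference_cm(ref[i, ])
    expect_lt(abs(accuracy_from_cm(cm) - ref$reported_accuracy[i]), 0.002)
    if (ref$classifier[i] != "lasso") {
      expect_lt(abs(f1_from_cm(cm) - ref$reported_f1[i]), 0.002)
      expect_lt(abs(mcnemar_statistic(cm) - ref$reported_chi2[i]), 0.01)
    } else {
      # the lasso rows' F1 follows the benign-positive convention
      expect_lt(abs(f1_from_cm(cm, positive = "benign") -
                    ref$reported_f1[i]), 0.002)
    }
  }
})

test_that("confusion matrix and accuracy behave on hand-checked cases", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(unname(cm), matrix(c(1L, 1L, 0L, 2L), 2, 2, byrow = TRUE))
  expect_equal(unname(confusion_matrix(c(0, 1), c(0, 1))),
               diag(c(1L, 1L)))
  expect_error(confusion_matrix(c(0, 1), c(0, 1, 1)), "lengths differ")

  set.seed(8)
  t500 <- rbinom(500, 1, 0.4); p500 <- rbinom(500, 1, 0.6)
  expect_equal(unname(confusion_matrix(t500, p500)),
               oracle_confusion(t500, p500))

  expect_equal(accuracy_from_cm(matrix(c(5, 0, 0, 9), 2, 2)), 1)
  expect_equal(f1_from_cm(matrix(c(5, 0, 0, 9), 2, 2)), 1)
  expect_equal(mcnemar_statistic(matrix(c(3, 4, 4, 9), 2, 2, byrow = TRUE)), 0)
  expect_warning(out <- mcnemar_statistic(matrix(c(3, 0, 0, 9), 2, 2)),
                 "no discordant")
  expect_equal(out, 0)
  # magnitude is invariant under swapping the off-diagonal cells
  expect_equal(mcnemar_statistic(matrix(c(3, 7, 2, 9), 2, 2, byrow = TRUE)),
               mcnemar_statistic(matrix(c(3, 2, 7, 9), 2, 2, byrow = TRUE)))
})

test_that("rank-based AUC equals the pairwise comparison oracle", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  set.seed(12)
  truth <- rbinom(200, 1, 0.45)
  score <- round(runif(200), 2)  # coarse grid forces ties
  expect_equal(auc_score(truth, score), oracle_auc(truth, score))
  expect_error(auc_score(rep(1, 5), runif(5)), "single-class")
})

test_that("all four classifiers separate a linearly separable toy table", {
  toy <- toy_feature_table(n = 80, seed = 2)
  for (kind in c("rf", "xgb", "gbc", "lasso")) {
    fitted <- train_classifier(toy, kind, "both")
    acc <- mean(predict(fitted, toy, type = "class") == toy$label)
    expect_equal(acc, 1.0, info = kind)
  }
})

test_that("training is deterministic and validates its inputs", {
  toy <- toy_feature_table(n = 60, seed = 3)
  a <- train_classifier(toy, "rf", "chi")
  b <- train_classifier(toy, "rf", "chi")
  expect_identical(predict(a, toy, type = "prob"),
                   predict(b, toy, type = "prob"))
  expect_error(train_classifier(toy, "rf", hyper = list(bogus = 1)),
               "unknown hyperparameter")
  one_class <- toy[toy$label == 0, ]
  expect_error(train_classifier(one_class, "rf"), "single class")
})

test_that("the lasso pins its largest coefficient on the informative feature", {
  toy <- toy_feature_table(n = 100, seed = 4, informative = "C8")
  fitted <- train_classifier(toy, "lasso", "ci")
  beta <- abs(as.numeric(stats::coef(fitted$model$model,
                                     s = fitted$model$lambda))[-1])
  expect_equal(which.max(beta), 8L)
})

test_that("cross-validation partitions exhaustively with balanced folds", {
  toy <- toy_feature_table(n = 83, seed = 5, informative = "CH3")
  # random-forest splits sit mid-gap, so a wide-margin toy problem is
  # perfect on every held-out fold (boosted stumps hug the class boundary
  # and may drop a held-out extreme into the gap)
  cv <- cross_validate(toy, "rf", "chi", k = 5, seed = 1)
  sizes <- table(cv$fold_id)
  expect_equal(sum(sizes), 83)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(unname(cv$mean["accuracy"]), 1.0)

  cv2 <- cross_validate(toy, "rf", "chi", k = 5, seed = 1)
  expect_identical(cv$fold_id, cv2$fold_id)
})

test_that("importance selection applies the strict 0.125 threshold", {
  toy <- toy_feature_table(n = 100, seed = 6, informative = "CH5")
  fitted <- train_classifier(toy, "rf", "chi")
  imp <- feature_importance(fitted)
  expect_equal(sum(imp$weights), 1)
  expect_equal(names(which.max(imp$weights)), "CH5")
  expect_true("CH5" %in% imp$selected)

  # a fully regularised lasso has no coefficients: weights fall back to the
  # uniform 1/8 = 0.125 profile, and the strict inequality selects nothing
  flat <- train_classifier(toy_feature_table(n = 60, seed = 7), "lasso",
                           "chi", hyper = list(C_grid = 1e-6))
  imp_flat <- feature_importance(flat)
  expect_equal(unname(imp_flat$weights), rep(0.125, 8))
  expect_length(imp_flat$selected, 0)
})
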