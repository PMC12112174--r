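# Four-classifier bench over the 16-feature table, with the metric chain
# used throughout: confusion matrix -> accuracy, F1 (malignant-positive),
# rank-based AUC (benign-positive), McNemar chi-squared on the confusion
# off-diagonals, plus stratified 5-fold cross-validation.

.default_hyper <- list(
  rf = list(n_estimators = 200, criterion = "gini", random_state = 0),
  xgb = list(n_estimators = 100, random_state = 2, criterion = "friedman_mse",
             learning_rate = 0.02, max_depth = 3),
  gbc = list(n_estimators = 100, learning_rate = 1.0, max_depth = 1,
             random_state = 0),
  lasso = list(penalty = "l1", solver = "saga", class_weight = "balanced",
               max_iter = 10000, random_state = 0,
               C_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000), cv_folds = 5)
)

.merge_hyper <- function(kind, hyper) {
  defaults <- .default_hyper[[kind]]
  unknown <- setdiff(names(hyper), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, hyper)
}

.feature_matrix <- function(records, feature_names) {
  miss <- setdiff(feature_names, names(records))
  if (length(miss)) stop("records lack feature column(s): ",
                         paste(miss, collapse = ", "))
  as.matrix(records[, feature_names, drop = FALSE])
}

#' Stratified train/test split of a feature table
#'
#' Splits by class so the 75:25 (default) ratio is preserved within each
#' class up to rounding; the per-class test count is `floor(n * f + 0.5)`.
#'
#' @param records Feature data frame with a `label` column in \{0, 1\}.
#' @param test_fraction Fraction held out, default 0.25.
#' @param seed Splitter seed (default 0).
#' @param stratified Set `FALSE` for a plain random split.
#' @return List with data frames `train` and `test`.
#' @export
stratified_split <- function(records, test_fraction = 0.25, seed = 0L,
                             stratified = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1, "label" %in% names(records))
  if (length(unique(records$label)) < 2) {
    stop("records contain a single class; cannot split for classification")
  }
  set.seed(as.integer(seed))
  n <- nrow(records)
  if (stratified) {
    test_idx <- integer(0)
    for (cl in sort(unique(records$label))) {
      idx <- which(records$label == cl)
      n_test <- floor(length(idx) * test_fraction + 0.5)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  } else {
    test_idx <- sample.int(n, floor(n * test_fraction + 0.5))
  }
  list(train = records[-sort(test_idx), , drop = FALSE],
       test = records[sort(test_idx), , drop = FALSE])
}

#' Train one of the four bench classifiers
#'
#' Available kinds and their default hyperparameters:
#' \describe{
#'   \item{`rf`}{random forest, 200 trees, Gini impurity, seed 0.}
#'   \item{`xgb`}{gradient-boosted trees, learning rate 0.02, depth 3,
#'     100 rounds, seed 2. The `friedman_mse` split criterion named by the
#'     scikit-learn boosting family is accepted and mapped to the backend's
#'     second-order gain criterion.}
#'   \item{`gbc`}{gradient boosting with depth-1 stumps, learning rate 1.0,
#'     100 rounds, seed 0 (the classical stump-boosting configuration).}
#'   \item{`lasso`}{L1-penalised logistic regression on standardized
#'     features with balanced class weights; the inverse regularisation
#'     strength C is tuned over \{0.001, ..., 1000\} by stratified 5-fold
#'     CV maximising ROC-AUC (ties resolved toward the smallest C).}
#' }
#'
#' @param records Training feature data frame (`label` in \{0, 1\}, both
#'   classes present).
#' @param kind One of `"rf"`, `"xgb"`, `"gbc"`, `"lasso"`.
#' @param feature_class `"chi"`, `"ci"` or `"both"` — which feature columns
#'   the model sees.
#' @param hyper Named list of hyperparameter overrides; unknown names are
#'   rejected.
#' @return A fitted object of class `lesion_classifier`.
#' @export
train_classifier <- function(records, kind = c("rf", "xgb", "gbc", "lasso"),
                             feature_class = c("chi", "ci", "both"),
                             hyper = list()) {
  kind <- match.arg(kind)
  feature_class <- match.arg(feature_class)
  hp <- .merge_hyper(kind, hyper)
  feature_names <- feature_class_columns(feature_class)
  x <- .feature_matrix(records, feature_names)
  y <- records$label
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("training data contain a single class")
  const <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    message("degenerate constant feature column(s): ",
            paste(feature_names[const], collapse = ", "))
  }

  fit <- switch(kind,
    rf = {
      set.seed(as.integer(hp$random_state))
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = hp$n_estimators, keep.inbag = TRUE)
    },
    xgb = , gbc = {
      set.seed(as.integer(hp$random_state))
      params <- list(objective = "binary:logistic", eta = hp$learning_rate,
                     max_depth = hp$max_depth, nthread = 1,
                     seed = as.integer(hp$random_state))
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = y),
                         nrounds = hp$n_estimators, verbose = 0)
    },
    lasso = .fit_lasso(x, y, hp)
  )

  obj <- structure(list(kind = kind, model = fit, hyper = hp,
                        feature_class = feature_class,
                        feature_names = feature_names,
                        train_x = x, train_y = y),
                   class = "lesion_classifier")
  if (kind == "lasso") {
    obj$center <- fit$center; obj$scale <- fit$scale
    obj$best_C <- fit$best_C
  }
  if (kind %in% c("xgb", "gbc")) {
    # xgboost estimates its own intercept (base margin); recover it once so
    # Shapley base values line up with raw margins
    marg1 <- predict(fit, xgboost::xgb.DMatrix(x[1, , drop = FALSE]),
                     outputmargin = TRUE)
    obj$base_margin <- marg1 - .sum_leaf_values(fit, x[1, , drop = FALSE],
                                                feature_names)
  }
  obj
}

# L1 logistic regression with scikit-learn-style C parametrisation:
# glmnet's (1/n) loss + lambda*|beta| matches sum-loss + (1/C)|beta| at
# lambda = 1 / (C * n)
.fit_lasso <- function(x, y, hp) {
  n <- nrow(x)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  z <- scale(x, center, scale_)
  w <- if (identical(hp$class_weight, "balanced")) {
    n / (2 * table(y)[as.character(y)])
  } else rep(1, n)
  w <- as.numeric(w)

  grid <- sort(hp$C_grid)
  lam <- 1 / (grid * n)
  set.seed(as.integer(hp$random_state))
  folds <- .stratified_folds(y, hp$cv_folds)
  auc_by_c <- matrix(NA_real_, hp$cv_folds, length(grid))
  for (f in seq_len(hp$cv_folds)) {
    tr <- folds != f
    ctr <- colMeans(x[tr, , drop = FALSE])
    sct <- apply(x[tr, , drop = FALSE], 2, stats::sd); sct[sct == 0] <- 1
    ztr <- scale(x[tr, , drop = FALSE], ctr, sct)
    zte <- scale(x[!tr, , drop = FALSE], ctr, sct)
    wtr <- w[tr]
    lam_f <- 1 / (grid * sum(tr))
    m <- glmnet::glmnet(ztr, y[tr], family = "binomial", alpha = 1,
                        lambda = sort(lam_f, decreasing = TRUE),
                        standardize = FALSE, weights = wtr,
                        maxit = hp$max_iter)
    for (ci in seq_along(grid)) {
      p <- as.numeric(predict(m, zte, s = lam_f[ci], type = "response",
                              exact = FALSE))
      auc_by_c[f, ci] <- auc_score(y[!tr], p)
    }
  }
  mean_auc <- colMeans(auc_by_c)
  best <- which.max(round(mean_auc, 12))  # first (smallest C) on ties
  m_full <- glmnet::glmnet(z, y, family = "binomial", alpha = 1,
                           lambda = sort(lam, decreasing = TRUE),
                           standardize = FALSE, weights = w,
                           maxit = hp$max_iter)
  list(model = m_full, lambda = lam[best], best_C = grid[best],
       center = center, scale = scale_, cv_auc = mean_auc, C_grid = grid)
}

# stratified fold assignment; per-class remainders go to the currently
# smallest folds so overall fold sizes differ by at most one
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  totals <- integer(k)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < k) stop("class ", cl, " has fewer members than folds")
    base <- length(idx) %/% k
    rem <- length(idx) %% k
    alloc <- rep(base, k)
    if (rem > 0) {
      grab <- order(totals, sample.int(k))[seq_len(rem)]
      alloc[grab] <- alloc[grab] + 1L
    }
    fold[idx] <- rep(seq_len(k), alloc)
    totals <- totals + alloc
  }
  fold
}

# sum of leaf contributions for rows of x under an xgboost model
.sum_leaf_values <- function(model, x, feature_names) {
  ens <- .xgb_ensemble(model, feature_names)
  .predict_ensemble_margin(ens, x)
}

#' Predict from a fitted bench classifier
#'
#' @param object A `lesion_classifier`.
#' @param newdata Feature data frame or matrix with the model's feature
#'   columns.
#' @param type `"prob"` for a two-column probability matrix (`malignant`,
#'   `benign`), `"class"` for 0/1 labels, `"score"` for the raw benign-
#'   direction score (vote fraction, boosting margin, or linear predictor).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.lesion_classifier <- function(object, newdata,
                                      type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) {
    newdata[, object$feature_names, drop = FALSE]
  } else {
    .feature_matrix(newdata, object$feature_names)
  }
  p_benign <- switch(object$kind,
    rf = predict(object$model, x, type = "prob")[, "1"],
    xgb = , gbc = as.numeric(predict(object$model, xgboost::xgb.DMatrix(x))),
    lasso = {
      z <- scale(x, object$center, object$scale)
      as.numeric(predict(object$model$model, z, s = object$model$lambda,
                         type = "response"))
    }
  )
  if (type == "prob") {
    return(cbind(malignant = 1 - p_benign, benign = p_benign))
  }
  if (type == "class") return(as.integer(p_benign >= 0.5))
  switch(object$kind,
    rf = as.numeric(p_benign),
    xgb = , gbc = as.numeric(predict(object$model,
                                     xgboost::xgb.DMatrix(x),
                                     outputmargin = TRUE)),
    lasso = {
      z <- scale(x, object$center, object$scale)
      as.numeric(predict(object$model$model, z, s = object$model$lambda,
                         type = "link"))
    }
  )
}

#' @export
print.lesion_classifier <- function(x, ...) {
  cat("lesion_classifier:", toupper(x$kind), "on", x$feature_class,
      "features (", length(x$feature_names), "columns,",
      nrow(x$train_x), "training samples )\n")
  if (x$kind == "lasso") cat("  selected C =", x$best_C, "\n")
  invisible(x)
}

#' 2x2 confusion matrix, malignant (0) indexed first
#'
#' @param truth,predicted Equal-length vectors of labels in \{0, 1\}.
#' @return 2x2 integer matrix `[[n00 n01] [n10 n11]]` with dimnames
#'   `truth`/`predicted` in class order `0, 1`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ")
  }
  stopifnot(all(truth %in% c(0, 1)), all(predicted %in% c(0, 1)))
  cm <- table(factor(truth, levels = c(0, 1)),
              factor(predicted, levels = c(0, 1)))
  out <- matrix(as.integer(cm), 2, 2,
                dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  out
}

#' Format a confusion matrix in the compact `[[a b][c d]]` print form
#' @param cm 2x2 matrix.
#' @return A string.
#' @export
format_cm <- function(cm) {
  sprintf("[[%d %d][%d %d]]", cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2])
}

#' Accuracy from a 2x2 confusion matrix
#' @param cm 2x2 confusion matrix (malignant first).
#' @return (n00 + n11) / total.
#' @export
accuracy_from_cm <- function(cm) {
  stopifnot(all(dim(cm) == 2), sum(cm) > 0)
  (cm[1, 1] + cm[2, 2]) / sum(cm)
}

#' F1 score from a 2x2 confusion matrix
#'
#' The malignant class (0, indexed first) is the positive class by default:
#' F1 = 2 n00 / (2 n00 + n01 + n10).
#'
#' @param cm 2x2 confusion matrix.
#' @param positive `"malignant"` (default) or `"benign"`.
#' @return F1 in \[0, 1\]; 0 with a warning when the positive class is
#'   absent from both truth and prediction.
#' @export
f1_from_cm <- function(cm, positive = c("malignant", "benign")) {
  positive <- match.arg(positive)
  stopifnot(all(dim(cm) == 2))
  if (positive == "benign") cm <- cm[2:1, 2:1]
  denom <- 2 * cm[1, 1] + cm[1, 2] + cm[2, 1]
  if (denom == 0) {
    warning("F1 undefined: positive class absent from truth and prediction")
    return(0)
  }
  2 * cm[1, 1] / denom
}

#' McNemar chi-squared statistic on the confusion off-diagonals
#'
#' chi^2 = (n01 - n10)^2 / (n01 + n10), without continuity correction by
#' default. A continuity-corrected variant ((|n01 - n10| - 1)^2 / (n01 +
#' n10)) is available but is not the reporting default.
#'
#' @param cm 2x2 confusion matrix.
#' @param correction `"none"` (default) or `"continuity"`.
#' @return Nonnegative statistic; 0 with a warning when both off-diagonal
#'   cells are 0.
#' @export
mcnemar_statistic <- function(cm, correction = c("none", "continuity")) {
  correction <- match.arg(correction)
  stopifnot(all(dim(cm) == 2))
  b <- cm[1, 2]; c <- cm[2, 1]
  if (b + c == 0) {
    warning("no discordant cells; statistic defined as 0")
    return(0)
  }
  num <- if (correction == "continuity") (abs(b - c) - 1)^2 else (b - c)^2
  num / (b + c)
}

#' Rank-based (Mann-Whitney) AUC with benign as the positive class
#'
#' Ties in the score contribute 1/2 via midranks.
#'
#' @param truth Labels in \{0, 1\}; both classes must be present.
#' @param probability_of_benign Numeric scores, higher = more benign.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(truth, probability_of_benign) {
  stopifnot(length(truth) == length(probability_of_benign),
            all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined for single-class truth")
  r <- rank(probability_of_benign)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Evaluate a fitted classifier on a held-out feature table
#'
#' @param fitted A `lesion_classifier`.
#' @param test Feature data frame with `label`.
#' @return A `performance_report` list: `accuracy`, `f1`, `auc`,
#'   `mcnemar_chi2`, `confusion`, `n`.
#' @export
evaluate_classifier <- function(fitted, test) {
  pred <- predict(fitted, test, type = "class")
  prob <- predict(fitted, test, type = "prob")
  cm <- confusion_matrix(test$label, pred)
  structure(list(
    accuracy = accuracy_from_cm(cm),
    f1 = f1_from_cm(cm),
    auc = auc_score(test$label, prob[, "benign"]),
    mcnemar_chi2 = mcnemar_statistic(cm),
    confusion = cm,
    n = nrow(test)
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  F1 %.4f  AUC %.4f  chi2 %.4f  %s (n=%d)\n",
              x$accuracy, x$f1, x$auc, x$mcnemar_chi2,
              format_cm(x$confusion), x$n))
  invisible(x)
}

#' Stratified k-fold cross-validation of one classifier configuration
#'
#' @param records Full feature table.
#' @param kind,feature_class,hyper As in [train_classifier()].
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List with `folds` (per-fold `performance_report`s) and `mean`
#'   (named vector of mean accuracy, F1, AUC and chi-squared).
#' @export
cross_validate <- function(records, kind, feature_class = "chi", k = 5,
                           seed = 0L, hyper = list()) {
  y <- records$label
  set.seed(as.integer(seed))
  fold <- .stratified_folds(y, k)
  reports <- lapply(seq_len(k), function(f) {
    fitted <- train_classifier(records[fold != f, , drop = FALSE], kind,
                               feature_class, hyper)
    evaluate_classifier(fitted, records[fold == f, , drop = FALSE])
  })
  metrics <- sapply(reports, function(r) {
    c(accuracy = r$accuracy, f1 = r$f1, auc = r$auc,
      mcnemar_chi2 = r$mcnemar_chi2)
  })
  list(folds = reports, mean = rowMeans(metrics), fold_id = fold)
}

#' Impurity (or coefficient) feature importance with threshold selection
#'
#' Tree models report split-impurity importance normalized to sum 1; the
#' lasso reports |standardized coefficient| normalized to sum 1. A feature
#' is selected when its weight strictly exceeds the threshold, whose default
#' 0.125 is the mean weight of 8 equally weighted features.
#'
#' @param fitted A `lesion_classifier`.
#' @param threshold Selection threshold (default 0.125).
#' @return An `importance_profile` list: `weights` (named, sums to 1),
#'   `threshold`, `selected` (character vector).
#' @export
feature_importance <- function(fitted, threshold = 0.125) {
  fn <- fitted$feature_names
  w <- switch(fitted$kind,
    rf = {
      imp <- fitted$model$importance[, "MeanDecreaseGini"]
      imp[fn]
    },
    xgb = , gbc = {
      it <- xgboost::xgb.importance(model = fitted$model)
      v <- stats::setNames(rep(0, length(fn)), fn)
      v[it$Feature] <- it$Gain
      v
    },
    lasso = {
      beta <- as.numeric(stats::coef(fitted$model$model,
                                     s = fitted$model$lambda))[-1]
      stats::setNames(abs(beta), fn)
    }
  )
  if (all(w == 0)) w[] <- 1 / length(w) else w <- w / sum(w)
  structure(list(weights = w, threshold = threshold,
                 selected = names(w)[w > threshold]),
            class = "importance_profile")
}
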