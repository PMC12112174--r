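# Shapley-value explanations. Tree models get exact attributions via the
# compiled leaf-wise algorithm in src/treeshap.cpp; the lasso gets the
# closed linear form; any model can fall back to a seeded permutation
# sampler. Attributions are on the model's benign-direction score scale
# (vote fraction for the forest, log-odds margin for boosting, linear
# predictor for the lasso): a positive value pushes the prediction toward
# benign (1), a negative one toward malignant (0).

# flatten an xgboost booster into parallel node arrays
.xgb_ensemble <- function(model, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  dt <- dt[order(dt$Tree, dt$Node), ]
  key <- paste(dt$Tree, dt$Node, sep = "-")
  gidx <- stats::setNames(seq_len(nrow(dt)) - 1L, dt$ID)
  is_leaf <- dt$Feature == "Leaf"
  feature <- rep(-1L, nrow(dt))
  feature[!is_leaf] <- match(dt$Feature[!is_leaf], feature_names) - 1L
  if (anyNA(feature[!is_leaf])) stop("booster uses unknown feature names")
  ens <- list(
    feature = feature,
    split = ifelse(is_leaf, 0, dt$Split),
    yes = ifelse(is_leaf, -1L, unname(gidx[dt$Yes])),
    no = ifelse(is_leaf, -1L, unname(gidx[dt$No])),
    value = ifelse(is_leaf, dt$Gain, 0),
    tree_offset = unname(gidx[key[dt$Node == 0]]),
    split_rule = "lt",
    n_features = length(feature_names)
  )
  ens$yes <- as.integer(ens$yes); ens$no <- as.integer(ens$no)
  ens$tree_offset <- as.integer(ens$tree_offset)
  ens
}

# flatten a randomForest classifier; leaf value is the benign-vote
# indicator scaled by 1/ntree so the ensemble sum equals the benign vote
# fraction reported by predict(type = "prob")
.rf_ensemble <- function(model, feature_names) {
  ntree <- model$ntree
  feats <- split_ <- yes <- no <- vals <- list()
  offs <- integer(ntree)
  pos <- 0L
  for (k in seq_len(ntree)) {
    tr <- randomForest::getTree(model, k, labelVar = FALSE)
    leaf <- tr[, "status"] == -1
    feats[[k]] <- ifelse(leaf, -1L, tr[, "split var"] - 1L)
    split_[[k]] <- ifelse(leaf, 0, tr[, "split point"])
    yes[[k]] <- ifelse(leaf, -1L, tr[, "left daughter"] - 1L + pos)
    no[[k]] <- ifelse(leaf, -1L, tr[, "right daughter"] - 1L + pos)
    vals[[k]] <- ifelse(leaf, (tr[, "prediction"] == 2) / ntree, 0)
    offs[k] <- pos
    pos <- pos + nrow(tr)
  }
  list(feature = as.integer(unlist(feats)), split = unlist(split_),
       yes = as.integer(unlist(yes)), no = as.integer(unlist(no)),
       value = unlist(vals), tree_offset = offs, split_rule = "le",
       n_features = length(feature_names))
}

#' Flatten a fitted tree model into a unified ensemble representation
#'
#' Node covers are computed by routing the model's own training data
#' through every tree: bootstrap in-bag counts weight the forest's trees,
#' unit weights the boosted ones.
#'
#' @param fitted A tree-kind `lesion_classifier` (`rf`, `xgb`, `gbc`).
#' @return A list of parallel node arrays (`feature`, `split`, `yes`, `no`,
#'   `value`, `cover`, `tree_offset`) plus `split_rule`, `base` and
#'   `n_features`.
#' @export
as_tree_ensemble <- function(fitted) {
  stopifnot(inherits(fitted, "lesion_classifier"))
  if (!fitted$kind %in% c("rf", "xgb", "gbc")) {
    stop("not a tree-based classifier: ", fitted$kind)
  }
  ens <- if (fitted$kind == "rf") {
    .rf_ensemble(fitted$model, fitted$feature_names)
  } else {
    .xgb_ensemble(fitted$model, fitted$feature_names)
  }
  W <- if (fitted$kind == "rf") {
    fitted$model$inbag * 1.0
  } else {
    matrix(1.0, nrow(fitted$train_x), length(ens$tree_offset))
  }
  ens$cover <- .tree_covers_cpp(ens$feature, ens$split, ens$yes, ens$no,
                                ens$tree_offset, fitted$train_x, W,
                                ens$split_rule == "lt")
  ens$base <- if (fitted$kind == "rf") 0 else fitted$base_margin
  ens
}

.predict_ensemble_margin <- function(ens, x) {
  .ensemble_margin_cpp(ens$feature, ens$split, ens$yes, ens$no, ens$value,
                       ens$tree_offset, x, ens$split_rule == "lt")
}

#' Shapley-value attributions for a fitted classifier
#'
#' For tree models the attributions are exact for the path-cover coalition
#' game (following a split when its feature is in the coalition, averaging
#' children by training cover otherwise) and satisfy local accuracy:
#' `rowSums(phi) + base` equals the model score for every record. The lasso
#' uses the closed linear form `beta_j * (z_j - mean(z_j))` over the
#' standardized training background. `method = "sampling"` is a seeded
#' permutation Monte Carlo estimator usable with any model kind.
#'
#' @param fitted A `lesion_classifier`.
#' @param records Feature data frame or matrix to explain.
#' @param method `"auto"` (exact tree / linear by kind), `"tree"`,
#'   `"linear"` or `"sampling"`.
#' @param nperm Permutations per record for the sampling estimator.
#' @param seed Seed for the sampling estimator.
#' @return Numeric matrix (records x features) of attributions with
#'   attributes `base` (score with no feature information) and `scale`.
#' @export
shap_values <- function(fitted, records,
                        method = c("auto", "tree", "linear", "sampling"),
                        nperm = 128, seed = 0L) {
  method <- match.arg(method)
  x <- if (is.matrix(records)) records[, fitted$feature_names, drop = FALSE]
       else .feature_matrix(records, fitted$feature_names)
  if (method == "auto") {
    method <- if (fitted$kind %in% c("rf", "xgb", "gbc")) "tree" else "linear"
  }
  scale_lab <- switch(fitted$kind, rf = "probability_benign",
                      lasso = "link", "margin")
  if (method == "tree") {
    ens <- as_tree_ensemble(fitted)
    res <- .treeshap_cpp(ens$feature, ens$split, ens$yes, ens$no, ens$value,
                         ens$cover, ens$tree_offset, x,
                         ens$split_rule == "lt")
    phi <- res$phi
    base <- res$base + ens$base
  } else if (method == "linear") {
    if (fitted$kind != "lasso") stop("linear attributions require the lasso")
    z <- scale(x, fitted$center, fitted$scale)
    zbg <- scale(fitted$train_x, fitted$center, fitted$scale)
    cf <- as.numeric(stats::coef(fitted$model$model, s = fitted$model$lambda))
    phi <- sweep(z, 2, colMeans(zbg)) %*% diag(cf[-1], length(cf) - 1)
    base <- cf[1] + sum(cf[-1] * colMeans(zbg))
  } else {
    phi <- .shap_sampling(fitted, x, nperm = nperm, seed = seed)
    base <- mean(predict(fitted, fitted$train_x, type = "score"))
  }
  dimnames(phi) <- list(NULL, fitted$feature_names)
  attr(phi, "base") <- base
  attr(phi, "scale") <- scale_lab
  phi
}

# permutation Monte Carlo Shapley estimate against the training background
.shap_sampling <- function(fitted, x, nperm, seed) {
  set.seed(as.integer(seed))
  p <- ncol(x)
  bg <- fitted$train_x
  phi <- matrix(0, nrow(x), p)
  for (i in seq_len(nrow(x))) {
    for (r in seq_len(nperm)) {
      ord <- sample.int(p)
      cur <- bg[sample.int(nrow(bg), 1), , drop = FALSE]
      prev <- predict(fitted, cur, type = "score")
      for (j in ord) {
        cur[1, j] <- x[i, j]
        now <- predict(fitted, cur, type = "score")
        phi[i, j] <- phi[i, j] + (now - prev) / nperm
        prev <- now
      }
    }
  }
  phi
}

#' Global SHAP explanation with per-class feature ranking
#'
#' Ranks features by the mean absolute Shapley value over the explained
#' records and assigns each feature to the class its values push toward:
#' a feature whose high values push the score toward benign (positive
#' correlation between feature value and attribution) lands in the benign
#' list, one whose high values push toward malignant in the malignant list.
#' Each list is ordered by descending mean |SV|; the stored score carries
#' the direction sign (negative = malignant-driving).
#'
#' @param fitted A `lesion_classifier`.
#' @param records Records to explain (typically the test set).
#' @param ... Passed to [shap_values()].
#' @return An `explanation_ranking` list with fields `explainer` ("SHAP"),
#'   `classifier`, `feature_class`, `sv` (the attribution matrix),
#'   `mean_abs_sv`, and `per_class_ranks` (`malignant`, `benign` data
#'   frames of `feature`, `score`).
#' @export
shap_explain <- function(fitted, records, ...) {
  sv <- shap_values(fitted, records, ...)
  x <- if (is.matrix(records)) records[, fitted$feature_names, drop = FALSE]
       else .feature_matrix(records, fitted$feature_names)
  mean_abs <- colMeans(abs(sv))
  dir <- vapply(seq_len(ncol(sv)), function(j) {
    if (stats::sd(x[, j]) == 0 || stats::sd(sv[, j]) == 0) {
      s <- sign(mean(sv[, j])); if (s == 0) 1 else s
    } else {
      sign(stats::cor(x[, j], sv[, j]))
    }
  }, numeric(1))
  score <- mean_abs * dir
  ord <- order(mean_abs, decreasing = TRUE)
  rk <- data.frame(feature = fitted$feature_names[ord], score = score[ord],
                   stringsAsFactors = FALSE)
  structure(list(
    explainer = "SHAP",
    classifier = fitted$kind,
    feature_class = fitted$feature_class,
    sv = sv,
    base = attr(sv, "base"),
    mean_abs_sv = mean_abs,
    per_class_ranks = list(
      malignant = rk[rk$score < 0, , drop = FALSE],
      benign = rk[rk$score >= 0, , drop = FALSE]
    )
  ), class = "explanation_ranking")
}

#' @export
print.explanation_ranking <- function(x, ...) {
  cat(x$explainer, "explanation for", toupper(x$classifier), "/",
      x$feature_class, "\n")
  for (cl in c("malignant", "benign")) {
    df <- x$per_class_ranks[[cl]]
    cat(sprintf("  %-9s: %s\n", cl,
                paste(sprintf("%s (%.4f)", df$feature, df$score),
                      collapse = ", ")))
  }
  invisible(x)
}
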