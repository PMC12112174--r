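#' Rank agreement among impurity importance, LIME and SHAP
#'
#' Compares the three views of one fitted classifier: the impurity (or
#' coefficient) importance selection, and the per-class top-k feature lists
#' from a LIME and a SHAP explanation. Reports top-k sets per class, all
#' pairwise intersections and the three-way intersection.
#'
#' @param importance An `importance_profile` from [feature_importance()].
#' @param lime,shap `explanation_ranking` objects over the same features.
#' @param k Top-k depth (default 3, the depth of the published per-class
#'   lists); must not exceed the number of features.
#' @return An `agreement_report` list: per class (`malignant`, `benign`) the
#'   top-k sets `importance`, `lime`, `shap`, the pairwise intersections and
#'   `common` (three-way intersection).
#' @export
rank_agreement <- function(importance, lime, shap, k = 3) {
  stopifnot(inherits(importance, "importance_profile"),
            identical(lime$explainer, "LIME"),
            identical(shap$explainer, "SHAP"))
  feats <- names(importance$weights)
  if (k > length(feats)) stop("k exceeds the number of features")
  if (!setequal(feats, c(lime$per_class_ranks$malignant$feature,
                         lime$per_class_ranks$benign$feature)) ||
      !setequal(feats, c(shap$per_class_ranks$malignant$feature,
                         shap$per_class_ranks$benign$feature))) {
    stop("importance, LIME and SHAP must cover the same feature set")
  }
  imp_topk <- names(sort(importance$weights, decreasing = TRUE))[seq_len(k)]
  per_class <- lapply(c(malignant = "malignant", benign = "benign"),
                      function(cl) {
    ltop <- utils::head(lime$per_class_ranks[[cl]]$feature, k)
    stop_ <- utils::head(shap$per_class_ranks[[cl]]$feature, k)
    list(importance = imp_topk, lime = ltop, shap = stop_,
         importance_lime = intersect(imp_topk, ltop),
         importance_shap = intersect(imp_topk, stop_),
         lime_shap = intersect(ltop, stop_),
         common = Reduce(intersect, list(imp_topk, ltop, stop_)))
  })
  structure(list(classifier = lime$classifier,
                 feature_class = lime$feature_class,
                 k = k,
                 selected = importance$selected,
                 per_class = per_class),
            class = "agreement_report")
}

#' Features common to several classifiers' explanations, per class
#'
#' Intersects the top-k per-class feature sets of one explainer across a
#' list of agreement reports (one per classifier), mirroring the boldface
#' "shared across classifiers" convention of published ranking tables.
#'
#' @param reports List of `agreement_report`s over the same feature class.
#' @param explainer `"lime"` or `"shap"`.
#' @return Named list with the `malignant` and `benign` intersections.
#' @export
common_across_classifiers <- function(reports, explainer = c("lime", "shap")) {
  explainer <- match.arg(explainer)
  stopifnot(length(reports) >= 1)
  lapply(c(malignant = "malignant", benign = "benign"), function(cl) {
    Reduce(intersect,
           lapply(reports, function(r) r$per_class[[cl]][[explainer]]))
  })
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement for", toupper(x$classifier), "/", x$feature_class,
      "(top-", x$k, ")\n")
  cat("  importance-selected:", paste(x$selected, collapse = ", "), "\n")
  for (cl in c("malignant", "benign")) {
    pc <- x$per_class[[cl]]
    cat(sprintf("  %-9s LIME: %-24s SHAP: %-24s common: %s\n", cl,
                paste(pc$lime, collapse = ","),
                paste(pc$shap, collapse = ","),
                paste(pc$common, collapse = ",")))
  }
  invisible(x)
}
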