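#' Reference benchmark results on the BUSI dataset
#'
#' Hold-out confusion matrices and reported metrics from the original
#' benchmark of the CHi/Ci feature classes on the public breast-ultrasound
#' (BUSI) dataset: four classifiers by two feature classes, test split of a
#' 211-malignant / 438-benign cohort. The confusion counts (`n00`, `n01`,
#' `n10`, `n11`; true class by predicted class, malignant first) are the
#' primary payload — the metric chain [accuracy_from_cm()], [f1_from_cm()]
#' and [mcnemar_statistic()] recomputes the reported accuracy, F1 and
#' chi-squared columns from them. The `reported_*` columns keep the values
#' as originally printed (3 decimals, benign-positive F1 for the lasso
#' rows; the lasso chi-squared values do not follow the off-diagonal
#' McNemar formula and are retained verbatim for reference only).
#'
#' @return Data frame with columns `feature_class`, `classifier`, `n00`,
#'   `n01`, `n10`, `n11`, `reported_accuracy`, `reported_f1`,
#'   `reported_auc`, `reported_chi2`.
#' @export
#' @examples
#' ref <- busi_reference_results()
#' cm <- matrix(unlist(ref[ref$classifier == "rf" &
#'                         ref$feature_class == "chi",
#'                         c("n00", "n01", "n10", "n11")]),
#'              2, 2, byrow = TRUE)
#' accuracy_from_cm(cm)   # 0.969
#' f1_from_cm(cm)         # 0.950
#' mcnemar_statistic(cm)  # 0.20
busi_reference_results <- function() {
  df <- read.csv(text = "feature_class,classifier,n00,n01,n10,n11,reported_accuracy,reported_f1,reported_auc,reported_chi2
chi,xgb,34,16,8,104,0.851,0.739,0.728,2.66
chi,rf,48,2,3,109,0.969,0.950,0.965,0.20
chi,gbc,41,9,4,109,0.919,0.863,0.872,1.92
chi,lasso,28,14,15,73,0.776,0.834,0.798,0.482
ci,xgb,44,14,5,99,0.882,0.822,0.816,4.26
ci,rf,57,2,3,100,0.969,0.957,0.967,0.20
ci,gbc,46,6,4,106,0.938,0.901,0.916,0.40
ci,lasso,29,13,18,70,0.761,0.818,0.812,0.429",
                 stringsAsFactors = FALSE)
  df
}

#' Rebuild a confusion matrix from one reference row
#'
#' @param row One-row data frame with `n00`, `n01`, `n10`, `n11`.
#' @return 2x2 confusion matrix (malignant first).
#' @export
reference_cm <- function(row) {
  matrix(c(row$n00, row$n01, row$n10, row$n11), 2, 2, byrow = TRUE,
         dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
}
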