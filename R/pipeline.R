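# End-to-end orchestration: features -> bench -> explanations -> agreement,
# with JSON artifacts and a provenance block per run.

#' Assemble a pipeline run configuration
#'
#' Either `images_dir` (image/mask pairs, optionally with a manifest) or
#' `features_csv` must be provided; when both exist the feature CSV wins,
#' so a rerun resumes after the image stage.
#'
#' @param out_dir Output directory for artifacts.
#' @param images_dir Optional lesion image directory (see
#'   [read_lesion_dir()]).
#' @param manifest Optional manifest CSV inside `images_dir`.
#' @param features_csv Optional precomputed feature CSV.
#' @param classifiers Subset of `c("rf", "xgb", "gbc", "lasso")`.
#' @param feature_classes Subset of `c("chi", "ci")` (or `"both"`).
#' @param split_seed,explain_seed Seeds for the train/test split and the
#'   LIME sampler (model seeds are the per-classifier defaults).
#' @param test_fraction Hold-out fraction, default 0.25.
#' @param importance_threshold Feature-selection threshold, default 0.125.
#' @param top_k Agreement list depth, default 3.
#' @param lime_instance Index (into the test set) of the instance LIME
#'   explains, default 1.
#' @param lime_samples Perturbation samples per LIME explanation, default
#'   5000.
#' @param cv_folds Folds for the cross-validated metrics, default 5.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, images_dir = NULL, manifest = NULL,
                       features_csv = NULL,
                       classifiers = c("rf", "xgb", "gbc", "lasso"),
                       feature_classes = c("chi", "ci"),
                       split_seed = 0L, explain_seed = 0L,
                       test_fraction = 0.25, importance_threshold = 0.125,
                       top_k = 3L, lime_instance = 1L, cv_folds = 5L,
                       lime_samples = 5000L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  feature_classes <- match.arg(feature_classes,
                               c("chi", "ci", "both"), several.ok = TRUE)
  if (is.null(images_dir) && is.null(features_csv)) {
    stop("config needs an images_dir or a features_csv")
  }
  for (path in c(images_dir, features_csv)) {
    if (!file.exists(path)) stop("input path does not exist: ", path)
  }
  structure(list(out_dir = out_dir, images_dir = images_dir,
                 manifest = manifest, features_csv = features_csv,
                 classifiers = classifiers, feature_classes = feature_classes,
                 split_seed = as.integer(split_seed),
                 explain_seed = as.integer(explain_seed),
                 test_fraction = test_fraction,
                 importance_threshold = importance_threshold,
                 top_k = as.integer(top_k),
                 lime_instance = as.integer(lime_instance),
                 cv_folds = as.integer(cv_folds),
                 lime_samples = as.integer(lime_samples)),
            class = "run_config")
}

.provenance <- function(config, inputs) {
  files <- inputs[file.exists(inputs) & !dir.exists(inputs)]
  list(tool = paste("lesionbench",
                    as.character(utils::packageVersion("lesionbench"))),
       config = unclass(config),
       input_checksums = as.list(tools::md5sum(files)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full classification-and-explanation pipeline
#'
#' Stages: feature extraction (or feature-CSV pass-through), stratified
#' split, training and evaluation of each requested classifier on each
#' feature class (hold-out metric chain plus cross-validated means, kept
#' distinct in the report), impurity-importance selection, LIME and SHAP
#' explanations, and the per-classifier rank-agreement report. All outputs
#' are deterministic for fixed seeds; `provenance.json` records the config,
#' input checksums and tool version.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the feature table, per-model reports and
#'   agreement reports; artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  features_path <- file.path(config$out_dir, "features.csv")
  if (!is.null(config$features_csv)) {
    say("reading feature table: ", config$features_csv)
    features <- read_feature_csv(config$features_csv)
    inputs <- config$features_csv
  } else {
    say("extracting features from ", config$images_dir)
    samples <- read_lesion_dir(config$images_dir, config$manifest)
    features <- extract_features_batch(samples)
    inputs <- config$images_dir
  }
  write_feature_csv(features, features_path)

  split <- stratified_split(features, config$test_fraction,
                            seed = config$split_seed)
  reports <- list()
  agreements <- list()
  for (fc in config$feature_classes) {
    agr_fc <- list()
    for (kind in config$classifiers) {
      say("training ", toupper(kind), " on ", fc)
      fitted <- train_classifier(split$train, kind, fc)
      hold <- evaluate_classifier(fitted, split$test)
      cv <- cross_validate(features, kind, fc, k = config$cv_folds,
                           seed = config$split_seed)
      imp <- feature_importance(fitted, config$importance_threshold)
      shap <- shap_explain(fitted, split$test)
      inst <- split$test[config$lime_instance, , drop = FALSE]
      lime <- lime_explain(fitted, inst, n_samples = config$lime_samples,
                           seed = config$explain_seed)
      agr <- rank_agreement(imp, lime, shap, k = config$top_k)

      report <- list(
        classifier = kind, feature_class = fc,
        hyperparameters = fitted$hyper,
        holdout = list(
          accuracy = hold$accuracy, f1 = hold$f1, auc = hold$auc,
          mcnemar_chi2 = hold$mcnemar_chi2,
          confusion = format_cm(hold$confusion), n = hold$n),
        cv_mean = as.list(cv$mean),
        cv_folds = lapply(cv$folds, function(r) {
          list(accuracy = r$accuracy, f1 = r$f1, auc = r$auc,
               mcnemar_chi2 = r$mcnemar_chi2, n = r$n)
        }),
        importance = list(weights = as.list(imp$weights),
                          threshold = imp$threshold,
                          selected = imp$selected),
        lime = list(instance = inst$sample_id,
                    prediction_probabilities =
                      as.list(lime$prediction_probabilities),
                    weights = as.list(lime$weights)),
        shap = list(mean_abs_sv = as.list(shap$mean_abs_sv),
                    malignant = shap$per_class_ranks$malignant$feature,
                    benign = shap$per_class_ranks$benign$feature),
        agreement = lapply(agr$per_class, function(pc) {
          lapply(pc, as.list)
        })
      )
      key <- paste(kind, fc, sep = "_")
      reports[[key]] <- report
      agr_fc[[kind]] <- agr
      .write_json(report, file.path(config$out_dir,
                                    paste0("report_", key, ".json")))
      for (cl in c("malignant", "benign")) {
        for (ex in list(lime, shap)) {
          df <- ex$per_class_ranks[[cl]]
          if (!nrow(df)) next
          fn <- sprintf("ranking_%s_%s_%s.csv", tolower(ex$explainer), key, cl)
          utils::write.csv(
            data.frame(class = cl, rank = seq_len(nrow(df)), df),
            file.path(config$out_dir, fn), row.names = FALSE)
        }
      }
    }
    agreements[[fc]] <- agr_fc
    .write_json(list(
      feature_class = fc,
      lime_common = common_across_classifiers(agr_fc, "lime"),
      shap_common = common_across_classifiers(agr_fc, "shap")
    ), file.path(config$out_dir, paste0("agreement_", fc, ".json")))
  }
  .write_json(.provenance(config, inputs),
              file.path(config$out_dir, "provenance.json"))
  say("artifacts written to ", config$out_dir)
  invisible(list(features = features, split = split, reports = reports,
                 agreements = agreements))
}
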