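# Local surrogate (LIME-style) explanations for tabular feature records.
# Quartile-discretising variant: the neighbourhood is sampled in bin space
# from the background marginals, the black-box model is queried on the
# undiscretised samples, and a kernel-weighted ridge model on the binary
# "same bin as the instance" representation yields signed local weights.

#' Explain one prediction with a local linear surrogate
#'
#' Each feature is discretised into quartile bins of the background
#' (training) data. Perturbed samples draw a bin per feature from the
#' background marginal bin frequencies and a uniform value within the bin's
#' background range; the interpretable representation is the indicator
#' "falls in the instance's bin". A ridge regression of the model's benign
#' probability on these indicators, weighted by an exponential kernel on
#' binary similarity to the instance, gives the local weights. Sign decides
#' the class a feature pushes toward: positive = benign (1), negative =
#' malignant (0).
#'
#' @param fitted A `lesion_classifier`.
#' @param instance One-row data frame or named numeric vector holding the
#'   model's feature columns.
#' @param background Feature data frame or matrix (defaults to the model's
#'   training matrix).
#' @param n_samples Number of perturbed samples (default 5000).
#' @param seed RNG seed; identical seeds give identical explanations.
#' @param kernel_width Kernel width; default `0.75 * sqrt(p)`.
#' @param ridge Ridge penalty of the surrogate (default 1).
#' @return An `explanation_ranking` with `explainer = "LIME"`, the signed
#'   per-feature `weights`, `prediction_probabilities` for the instance and
#'   per-class ranked lists.
#' @export
lime_explain <- function(fitted, instance, background = NULL,
                         n_samples = 5000, seed = 0L, kernel_width = NULL,
                         ridge = 1) {
  fn <- fitted$feature_names
  if (is.null(background)) background <- fitted$train_x
  bg <- if (is.matrix(background)) background[, fn, drop = FALSE]
        else .feature_matrix(background, fn)
  if (is.data.frame(instance)) instance <- unlist(instance[1, fn])
  if (is.null(names(instance))) stop("instance must carry feature names")
  if (!all(fn %in% names(instance))) {
    stop("instance lacks the model's feature class (", fitted$feature_class,
         ") columns")
  }
  xi <- as.numeric(instance[fn])
  p <- length(fn)
  if (all(apply(bg, 2, stats::sd) == 0)) {
    stop("zero-variance background: cannot build a neighbourhood")
  }
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)

  set.seed(as.integer(seed))
  # quartile discretisation of the background
  bins <- lapply(seq_len(p), function(j) {
    br <- unique(unname(stats::quantile(bg[, j], c(0.25, 0.5, 0.75))))
    lo <- min(bg[, j], xi[j]); hi <- max(bg[, j], xi[j])
    edges <- c(lo, br, hi)
    freq <- tabulate(findInterval(bg[, j], br, left.open = TRUE) + 1L,
                     nbins = length(br) + 1L)
    if (sum(freq) == 0) freq <- rep(1, length(br) + 1L)
    list(breaks = br, edges = edges, freq = freq / sum(freq))
  })
  inst_bin <- vapply(seq_len(p), function(j) {
    findInterval(xi[j], bins[[j]]$breaks, left.open = TRUE) + 1L
  }, integer(1))

  Xpert <- matrix(0, n_samples, p, dimnames = list(NULL, fn))
  Z <- matrix(0, n_samples, p)
  for (j in seq_len(p)) {
    bj <- bins[[j]]
    k <- length(bj$freq)
    drawn <- sample.int(k, n_samples, replace = TRUE, prob = bj$freq)
    lo <- bj$edges[drawn]; hi <- bj$edges[drawn + 1]
    Xpert[, j] <- stats::runif(n_samples, lo, hi)
    Z[, j] <- (drawn == inst_bin[j]) * 1
  }
  # first sample is the instance itself, as in the reference formulation
  Xpert[1, ] <- xi
  Z[1, ] <- 1

  yhat <- predict(fitted, Xpert, type = "prob")[, "benign"]
  d <- sqrt(rowSums((Z - 1)^2))
  w <- exp(-d^2 / kernel_width^2)

  # weighted ridge with unpenalised intercept
  Zc <- cbind(1, Z)
  A <- crossprod(Zc * w, Zc) + diag(c(0, rep(ridge, p)))
  beta <- solve(A, crossprod(Zc * w, yhat))[-1]
  weights <- stats::setNames(as.numeric(beta), fn)

  prob <- predict(fitted, matrix(xi, 1, dimnames = list(NULL, fn)),
                  type = "prob")
  ord <- order(abs(weights), decreasing = TRUE)
  rk <- data.frame(feature = fn[ord], score = unname(weights[ord]),
                   stringsAsFactors = FALSE)
  structure(list(
    explainer = "LIME",
    classifier = fitted$kind,
    feature_class = fitted$feature_class,
    weights = weights,
    prediction_probabilities = c(malignant = unname(prob[1, "malignant"]),
                                 benign = unname(prob[1, "benign"])),
    n_samples = n_samples,
    seed = as.integer(seed),
    per_class_ranks = list(
      malignant = rk[rk$score < 0, , drop = FALSE],
      benign = rk[rk$score >= 0, , drop = FALSE]
    )
  ), class = "explanation_ranking")
}
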