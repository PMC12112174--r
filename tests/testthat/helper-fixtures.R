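# Shared fixtures, built in code. Cohorts are memoised so several test
# files can reuse the same generated data without paying generation twice.

.fixture_cache <- new.env(parent = emptyenv())

cached_cohort_features <- function(n_malignant, n_benign, seed) {
  key <- paste(n_malignant, n_benign, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cohort <- generate_cohort(n_malignant, n_benign, seed = seed)
    .fixture_cache[[key]] <- extract_features_batch(cohort$samples)
  }
  .fixture_cache[[key]]
}

# random valid lesion sample (image + mask) of the given size
random_sample <- function(M, N, label = 1L) {
  img <- matrix(sample(0:255, M * N, replace = TRUE), M, N)
  msk <- matrix(0L, M, N)
  while (sum(msk) == 0) msk <- matrix(rbinom(M * N, 1, 0.3), M, N)
  lesion_sample(img, msk, label)
}

# feature table with a clean single-feature signal: high C8 <=> malignant;
# all 16 columns satisfy the sum-to-one invariants
toy_feature_table <- function(n = 120, seed = 1, informative = "C8") {
  set.seed(seed)
  raw_ch <- matrix(runif(n * 8), n, 8)
  raw_c <- matrix(runif(n * 8), n, 8)
  label <- rep(c(0L, 1L), length.out = n)
  hot <- ifelse(label == 0, 12, 0.05)
  if (grepl("^CH", informative)) {
    raw_ch[, as.integer(sub("CH", "", informative))] <- hot
  } else {
    raw_c[, as.integer(sub("C", "", informative))] <- hot
  }
  ch <- raw_ch / rowSums(raw_ch)
  cc <- raw_c / rowSums(raw_c)
  colnames(ch) <- paste0("CH", 1:8)
  colnames(cc) <- paste0("C", 1:8)
  data.frame(sample_id = sprintf("t%03d", seq_len(n)), ch, cc, label = label,
             stringsAsFactors = FALSE)
}

# random feature records (no class signal) for IO round-trip tests
random_feature_records <- function(n, seed = 1) {
  set.seed(seed)
  ch <- matrix(runif(n * 8), n, 8); ch <- ch / rowSums(ch)
  cc <- matrix(runif(n * 8), n, 8); cc <- cc / rowSums(cc)
  colnames(ch) <- paste0("CH", 1:8); colnames(cc) <- paste0("C", 1:8)
  data.frame(sample_id = sprintf("r%03d", seq_len(n)), ch, cc,
             label = rep(c(0L, 1L), length.out = n), stringsAsFactors = FALSE)
}
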