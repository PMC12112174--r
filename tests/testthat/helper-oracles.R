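# Independent reference implementations used as oracles. These deliberately
# re-read the feature definitions literally (nested loops, Kronecker delta,
# exhaustive subset enumeration) and share no code with the package paths
# they check.

# nested-loop tally of the 16 features from an image + binary mask
oracle_features <- function(image, mask) {
  M <- nrow(image); N <- ncol(image)
  roi <- image * mask
  tally <- numeric(256)
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      for (i in 0:255) {
        if (roi[m, n] == i) tally[i + 1] <- tally[i + 1] + 1
      }
    }
  }
  ch <- numeric(8)
  for (k in 1:8) {
    for (i in (32 * (k - 1)):(32 * k - 1)) ch[k] <- ch[k] + tally[i + 1]
  }
  ch <- ch / (M * N)
  s <- sum(mask)
  cd <- numeric(8)
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      if (mask[m, n] == 1) {
        k <- image[m, n] %/% 32 + 1
        cd[k] <- cd[k] + 1
      }
    }
  }
  list(CH = ch, C = cd / s, S = s)
}

# four-counter confusion tally
oracle_confusion <- function(truth, pred) {
  n00 <- n01 <- n10 <- n11 <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 0 && pred[i] == 0) n00 <- n00 + 1L
    if (truth[i] == 0 && pred[i] == 1) n01 <- n01 + 1L
    if (truth[i] == 1 && pred[i] == 0) n10 <- n10 + 1L
    if (truth[i] == 1 && pred[i] == 1) n11 <- n11 + 1L
  }
  matrix(c(n00, n01, n10, n11), 2, 2, byrow = TRUE)
}

# O(n^2) pairwise AUC, benign (1) positive, ties count 1/2
oracle_auc <- function(truth, score) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# cover-weighted expected tree output given a feature coalition S
# (1-based feature indices); node is a 0-based index into the flattened
# ensemble arrays
oracle_expvalue <- function(ens, node, x, S) {
  f <- ens$feature[node + 1]
  if (f < 0) return(ens$value[node + 1])
  yes <- ens$yes[node + 1]; no <- ens$no[node + 1]
  if ((f + 1) %in% S) {
    go <- if (ens$split_rule == "lt") x[f + 1] < ens$split[node + 1]
          else x[f + 1] <= ens$split[node + 1]
    oracle_expvalue(ens, if (go) yes else no, x, S)
  } else {
    (ens$cover[yes + 1] * oracle_expvalue(ens, yes, x, S) +
     ens$cover[no + 1] * oracle_expvalue(ens, no, x, S)) /
      ens$cover[node + 1]
  }
}

# brute-force Shapley values by full 2^p subset enumeration
oracle_shapley <- function(ens, x, p) {
  vgame <- function(S) {
    s <- 0
    for (t in ens$tree_offset) s <- s + oracle_expvalue(ens, t, x, S)
    s
  }
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  v <- vapply(subsets, vgame, numeric(1))
  key <- function(S) sum(2^(S - 1)) + 1
  phi <- numeric(p)
  for (i in seq_len(p)) {
    for (S in subsets) {
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[i] <- phi[i] + w * (v[key(c(S, i))] - v[key(S)])
    }
  }
  phi
}

# 8-connected component count of a logical matrix (flood fill)
oracle_components <- function(bw) {
  lab <- matrix(0L, nrow(bw), ncol(bw))
  cur <- 0L
  for (i in seq_len(nrow(bw))) for (j in seq_len(ncol(bw))) {
    if (bw[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          a <- q[1] + di; b <- q[2] + dj
          if (a >= 1 && a <= nrow(bw) && b >= 1 && b <= ncol(bw) &&
              bw[a, b] && lab[a, b] == 0L) {
            lab[a, b] <- cur
            queue[[length(queue) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  cur
}
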