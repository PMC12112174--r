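test_that("mask binarization thresholds at nonzero and rejects empty masks", {
  expect_equal(binarize_mask(matrix(c(0, 255, 255, 0), 2, 2, byrow = TRUE)),
               matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  expect_equal(binarize_mask(matrix(255, 3, 3)), matrix(1L, 3, 3))
  expect_error(binarize_mask(matrix(0, 3, 3)), "empty lesion")
})

test_that("ROI is the elementwise product and S counts mask pixels", {
  s <- lesion_sample(matrix(c(10L, 30L, 200L, 40L), 2, 2),
                     matrix(c(1L, 0L, 0L, 1L), 2, 2), label = 1)
  roi <- make_roi(s)
  expect_equal(roi$values, matrix(c(10L, 0L, 0L, 40L), 2, 2))
  expect_equal(roi$S, 2)

  full <- lesion_sample(matrix(7L, 3, 4), matrix(1L, 3, 4), label = 0)
  expect_equal(make_roi(full)$values, full$image)
  expect_equal(make_roi(full)$S, 12)

  set.seed(11)
  rs <- random_sample(50, 50)
  expect_equal(make_roi(rs)$S, sum(rs$mask != 0))

  expect_error(lesion_sample(matrix(0L, 2, 2), matrix(1L, 2, 3), 1),
               "dimensions differ")
})

test_that("normalized histogram matches a per-level tally and sums to one", {
  all0 <- normalized_histogram(matrix(0L, 4, 4))
  expect_equal(unname(all0$h[1]), 1)
  expect_equal(sum(all0$h), 1)

  two <- normalized_histogram(matrix(c(0L, 0L, 100L, 100L), 2, 2))
  expect_equal(unname(two$h[c("0", "100")]), c(0.5, 0.5))

  set.seed(5)
  v <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  h <- normalized_histogram(v)
  tally <- vapply(0:255, function(i) sum(v == i), numeric(1)) / (64 * 64)
  expect_equal(unname(h$h), tally)
  expect_identical(sum(h$counts), 64L * 64L)
  expect_equal(sum(h$h), 1, tolerance = 1e-12)
})

test_that("bounded-histogram bins are the inclusive 32-level partitions", {
  h1 <- numeric(256); h1[1] <- 1
  expect_equal(unname(bounded_histogram_features(h1)),
               c(1, 0, 0, 0, 0, 0, 0, 0))

  # bin-edge membership: 64 and 95 are both bin 3, 200 is bin 7
  h2 <- numeric(256); h2[64 + 1] <- 0.25; h2[95 + 1] <- 0.25; h2[200 + 1] <- 0.5
  ch <- bounded_histogram_features(h2)
  expect_equal(unname(ch[c(3, 7)]), c(0.5, 0.5))
  expect_equal(sum(ch), 1)

  set.seed(6)
  hr <- runif(256); hr <- hr / sum(hr)
  direct <- vapply(1:8, function(k) {
    acc <- 0
    for (i in (32 * (k - 1)):(32 * k - 1)) acc <- acc + hr[i + 1]
    acc
  }, numeric(1))
  expect_equal(unname(bounded_histogram_features(hr)), direct,
               tolerance = 1e-12)
})

test_that("grayscale density counts in-mask pixels per bin over lesion area", {
  img <- matrix(0L, 4, 4); msk <- matrix(0L, 4, 4)
  img[1:2, ] <- 100L; msk[1:2, ] <- 1L
  s <- lesion_sample(img, msk, 1)
  cd <- grayscale_density_features(make_roi(s))
  expect_equal(unname(cd[4]), 1)
  expect_equal(sum(cd), 1)

  # one pixel per bin 1/2/4/8 — and in-mask zeros count in bin 1
  img2 <- matrix(0L, 2, 2); img2[] <- c(0L, 40L, 100L, 250L)
  cd2 <- grayscale_density_features(img2, matrix(1L, 2, 2))
  expect_equal(unname(cd2[c(1, 2, 4, 8)]), rep(0.25, 4))

  # CHi vs Ci normalization difference on a half-frame lesion
  fr <- extract_features(s)
  expect_equal(fr$C4, 1)
  expect_equal(fr$CH4, 0.5)
  expect_equal(fr$CH1, 0.5)  # background zeros land in bin 1
})

test_that("extracted records satisfy the partition and scaling identities", {
  set.seed(21)
  for (rep in 1:20) {
    M <- sample(8:40, 1); N <- sample(8:40, 1)
    s <- random_sample(M, N, label = sample(0:1, 1))
    fr <- extract_features(s)
    ch <- unlist(fr[paste0("CH", 1:8)])
    cd <- unlist(fr[paste0("C", 1:8)])
    S <- sum(s$mask)
    # the underlying bin tallies partition the frame and the lesion
    expect_identical(sum(round(ch * M * N)), as.numeric(M * N))
    expect_identical(sum(round(cd * S)), as.numeric(S))
    expect_equal(sum(ch), 1, tolerance = 1e-12)
    expect_equal(sum(cd), 1, tolerance = 1e-12)
    # exact integer count identity for bins 2..8
    expect_equal(unname(ch[2:8] * M * N), unname(cd[2:8] * S))
    # bin 1 differs by exactly the count of background zeros
    expect_equal(ch[[1]] * M * N - cd[[1]] * S, sum(s$mask == 0))
  }
})

test_that("features are permutation invariant and mask growth into zero background only moves bin 1", {
  set.seed(31)
  s <- random_sample(20, 20)
  fr <- extract_features(s)

  # shuffle pixel positions jointly with the mask
  perm <- sample(400)
  img2 <- matrix(s$image[perm], 20, 20)
  msk2 <- matrix(s$mask[perm], 20, 20)
  fr2 <- extract_features(lesion_sample(img2, msk2, s$label))
  expect_equal(fr2[, -1], fr[, -1])

  # an image whose background is exactly zero: growing the mask outward
  # adds only zero-valued pixels, so bins 2..8 counts are unchanged
  img <- matrix(0L, 16, 16)
  msk <- matrix(0L, 16, 16); msk[5:10, 5:10] <- 1L
  img[msk == 1] <- sample(32:255, sum(msk), replace = TRUE)
  small <- extract_features(lesion_sample(img, msk, 1))
  big_mask <- msk; big_mask[4:11, 4:11] <- 1L
  big <- extract_features(lesion_sample(img, big_mask, 1))
  ch_cols <- paste0("CH", 2:8)
  expect_equal(unlist(big[ch_cols]) * 256, unlist(small[ch_cols]) * 256)
  expect_gt(big$C1, small$C1)
})

test_that("feature extraction agrees exactly with the nested-loop oracle", {
  set.seed(41)
  for (rep in 1:8) {
    s <- random_sample(sample(8:32, 1), sample(8:32, 1))
    fr <- extract_features(s)
    orc <- oracle_features(s$image, s$mask)
    expect_identical(unname(unlist(fr[paste0("CH", 1:8)])), orc$CH)
    expect_identical(unname(unlist(fr[paste0("C", 1:8)])), orc$C)
  }
})
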