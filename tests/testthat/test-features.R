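test_that("patch features stack neighborhoods as documented", {
  # constant image: every stacked column is the constant vector
  Y <- FeatureImage(matrix(2.5, 2, 12), c(3, 4))
  F <- patchFeatures(Y)
  expect_equal(nrow(featureMatrix(F)), 16)  # l = 2, Nb = 8 -> R^16
  expect_true(all(featureMatrix(F) == 2.5))

  # interior pixel of a ramp: hand-indexed loop over the 8 offsets
  vals <- matrix(seq_len(2 * 20), 2)        # 4 x 5 image, 2 features
  Y <- FeatureImage(vals, c(4, 5))
  F <- patchFeatures(Y)
  p <- (3 - 1) * 5 + 3                       # pixel (3, 3)
  want <- c()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    q <- (3 + dr - 1) * 5 + (3 + dc)
    want <- c(want, vals[, q])
  }
  expect_equal(featureMatrix(F)[, p], want)

  # border pixel: replicate padding clamps out-of-image offsets
  q11 <- function(dr, dc) (max(1, min(4, 1 + dr)) - 1) * 5 +
    max(1, min(5, 1 + dc))
  want <- c()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    want <- c(want, vals[, q11(dr, dc)])
  }
  expect_equal(featureMatrix(F)[, 1], want)

  # window must be odd
  expect_error(patchFeatures(Y, window = 4), "odd")
  # includeCenter grows the stack to window^2 blocks
  expect_equal(nrow(featureMatrix(patchFeatures(Y, includeCenter = TRUE))),
               18)
})

test_that("patch features commute with spatial transposition", {
  set.seed(4)
  vals <- matrix(rnorm(3 * 20), 3)
  Y <- FeatureImage(vals, c(4, 5))
  F <- patchFeatures(Y)
  # transpose the image: pixel (r, c) -> (c, r), offsets (dr, dc) -> (dc, dr)
  mt <- matrix(0, 3, 20)
  for (r in 1:4) for (cc in 1:5) {
    p <- (r - 1) * 5 + cc          # original
    pt <- (cc - 1) * 4 + r         # transposed
    mt[, pt] <- vals[, p]
  }
  Ft <- patchFeatures(FeatureImage(mt, c(5, 4)))
  # offsets row-major in original = (dr, dc); in transposed, offset b'
  # with (dc, dr).  Build the row permutation taking F to Ft.
  off <- expand.grid(dc = -1:1, dr = -1:1)[, c("dr", "dc")]
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  rowPerm <- integer(24)
  for (b in 1:8) {
    bt <- which(off$dr == off$dc[b] & off$dc == off$dr[b])
    rowPerm[(b - 1) * 3 + 1:3] <- (bt - 1) * 3 + 1:3
  }
  for (r in 1:4) for (cc in 1:5) {
    p <- (r - 1) * 5 + cc
    pt <- (cc - 1) * 4 + r
    expect_equal(featureMatrix(Ft)[, pt],
                 featureMatrix(F)[rowPerm, p])
  }
})

test_that("feature distance and similarity index behave as a metric pair", {
  expect_equal(featureDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(featureDistance(c(3, 4, 0, 0), c(0, 0, 0, 0)), 5)
  set.seed(8)
  a <- rnorm(16); b <- rnorm(16)
  loop <- 0
  for (i in 1:16) loop <- loop + (a[i] - b[i])^2
  expect_lt(abs(featureDistance(a, b) - sqrt(loop)), 1e-12)
  expect_error(featureDistance(1:3, 1:4), "length")

  expect_equal(similarityIndex(a, a, epsilon = 1e-3), 1000)
  b2 <- a; b2[1] <- a[1] + 0.999
  expect_equal(similarityIndex(a, b2, epsilon = 1e-3), 1.0)
  expect_equal(similarityIndex(a, b), similarityIndex(b, a))
  # strictly decreasing in distance, max 1/eps iff distance 0
  d <- seq(0, 2, by = 0.25)
  s <- 1 / (d + 1e-3)
  expect_true(all(diff(s) < 0))
  expect_error(similarityIndex(a, b, epsilon = 0), "positive")
})

test_that("class centroids are per-class means of stacked features", {
  set.seed(12)
  Y <- FeatureImage(matrix(rnorm(2 * 16), 2), c(4, 4))
  F <- patchFeatures(Y)
  # one marked pixel per class: centroid is that pixel's column
  mask1 <- LabelMask(matrix(c(1, rep(0, 14), 2), 4, 4, byrow = TRUE))
  cents <- classCentroids(F, mask1)
  expect_equal(cents[, 1], featureMatrix(F)[, 1])
  expect_equal(cents[, 2], featureMatrix(F)[, 16])
  # two marked pixels: (u + v) / 2
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[1, 2] <- 1; m[4, 4] <- 2
  cents <- classCentroids(F, LabelMask(m))
  expect_equal(cents[, 1],
               (featureMatrix(F)[, 1] + featureMatrix(F)[, 2]) / 2)
  # random marking vs explicit accumulation
  lab <- sample(0:2, 16, TRUE); lab[1:2] <- 1:2
  maskR <- LabelMask(matrix(lab, 4, 4, byrow = TRUE))
  cents <- classCentroids(F, maskR)
  for (k in 1:2) {
    acc <- numeric(16); n <- 0
    for (p in which(lab == k)) { acc <- acc + featureMatrix(F)[, p]; n <- n + 1 }
    expect_lt(max(abs(cents[, k] - acc / n)), 1e-12)
  }
})

test_that("similarity to labels matches the double-loop oracle", {
  set.seed(30)
  Y <- FeatureImage(matrix(rnorm(2 * 16), 2), c(4, 4))
  F <- patchFeatures(Y)
  lab <- rep(0L, 16); lab[c(1, 6)] <- 1L; lab[c(11, 16)] <- 2L
  mask <- LabelMask(matrix(lab, 4, 4, byrow = TRUE))
  cents <- classCentroids(F, mask)
  S <- similarityToLabels(F, cents, epsilon = 1e-3)
  for (p in 1:16) for (k in 1:2) {
    d <- sqrt(sum((featureMatrix(F)[, p] - cents[, k])^2))
    expect_lt(abs(S[p, k] - 1 / (d + 1e-3)), 1e-12)
  }
  # a pixel whose stacked vector equals the centroid scores 1/eps
  mask1 <- LabelMask(matrix(c(1, rep(0, 14), 2), 4, 4, byrow = TRUE))
  S1 <- similarityToLabels(F, classCentroids(F, mask1), epsilon = 1e-3)
  expect_equal(S1[1, 1], 1000)
  expect_equal(S1[16, 2], 1000)
})

test_that("Monte-Carlo squared patch distances match the noise identities", {
  set.seed(99)
  n <- 16                                   # l * Nb
  fa <- runif(n, 1, 4); fb <- runif(n, 1, 4)
  draws <- 20000
  # Gaussian: E d^2 = ||fa - fb||^2 + 2 n sigma^2
  sigma <- 0.7
  d2 <- colSums((matrix(rnorm(n * draws, fa, sigma), n) -
                 matrix(rnorm(n * draws, fb, sigma), n))^2)
  want <- sum((fa - fb)^2) + 2 * n * sigma^2
  se <- sd(d2) / sqrt(draws)
  expect_lt(abs(mean(d2) - want), 4 * se)
  # Poisson: E d^2 = ||fa - fb||^2 + ||fa + fb||_1
  d2p <- colSums((matrix(rpois(n * draws, fa), n) -
                  matrix(rpois(n * draws, fb), n))^2)
  wantp <- sum((fa - fb)^2) + sum(fa + fb)
  sep <- sd(d2p) / sqrt(draws)
  expect_lt(abs(mean(d2p) - wantp), 4 * sep)
})
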