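# small random marked sample used by several blocks
randomSample <- function(m, nT, nM, seed) {
  set.seed(seed)
  sizes <- tabulate(sample(nM, nT - nM, replace = TRUE), nbins = nM) + 1L
  X0 <- matrix(rnorm(m * nT), m) +
    matrix(rnorm(m * nM, sd = 2), m)[, rep(seq_len(nM), sizes)]
  cube <- HyperCube(array(X0, c(m, 1, nT)))
  mask <- LabelMask(matrix(rep(seq_len(nM), sizes), 1))
  buildMarkedSample(cube, mask)
}

test_that("marked sample gathers spectra, sizes and means correctly", {
  # constant data: every mean is the common spectrum
  v <- c(1, 2, 3, 4)
  cube <- HyperCube(array(v, c(4, 2, 3)))
  mask <- LabelMask(matrix(c(1, 1, 1, 2, 2, 2), 2, 3))
  s <- buildMarkedSample(cube, mask)
  expect_equal(s$mean, v)
  expect_equal(s$means[, 1], v)
  expect_equal(s$means[, 2], v)
  expect_equal(ncol(s$X), sum(labelMatrix(mask) > 0))

  # random data: means against direct per-column summation
  s <- randomSample(5, 17, 3, seed = 11)
  for (k in 1:3) {
    cols <- s$X[, s$group == k, drop = FALSE]
    direct <- rowSums(cols) / ncol(cols)
    expect_lt(max(abs(s$means[, k] - direct)), 1e-12)
  }
  expect_equal(sum(s$sizes), ncol(s$X))
  # weighted region means reproduce the global mean
  expect_lt(max(abs(s$means %*% s$sizes / sum(s$sizes) - s$mean)), 1e-12)
})

test_that("scatter factors reproduce the scatter matrices", {
  # constant data centers to zero
  cube <- HyperCube(array(2, c(3, 1, 6)))
  mask <- LabelMask(matrix(c(1, 1, 1, 2, 2, 2), 1))
  fac <- scatterFactors(buildMarkedSample(cube, mask))
  expect_true(all(fac$H == 0))
  expect_true(all(fac$Hb == 0))

  # H H^T against the explicit double-loop total scatter (5 bands, 6 px)
  s <- randomSample(5, 6, 2, seed = 3)
  fac <- scatterFactors(s)
  Sloop <- matrix(0, 5, 5)
  for (j in seq_len(6)) {
    d <- s$X[, j] - s$mean
    Sloop <- Sloop + outer(d, d) / 6
  }
  expect_lt(max(abs(fac$H %*% t(fac$H) - Sloop)), 1e-10)
  # explicit between-class scatter
  Sb <- matrix(0, 5, 5)
  for (k in 1:2) {
    d <- s$means[, k] - s$mean
    Sb <- Sb + s$sizes[k] / 6 * outer(d, d)
  }
  expect_lt(max(abs(fac$Hb %*% t(fac$Hb) - Sb)), 1e-10)
  # centering: columns of H sum to zero
  expect_lt(max(abs(rowSums(fac$H))), 1e-12)

  # rank(Hb) <= nM - 1
  fac3 <- scatterFactors(randomSample(8, 30, 3, seed = 5))
  expect_equal(sum(svd(fac3$Hb)$d > 1e-10), 2)
})

test_that("lambda = 0 projection attains the generalized-eigenvalue optimum", {
  for (seed in 1:5) {
    s <- randomSample(10, 40, sample(2:5, 1), seed = seed)
    fac <- scatterFactors(s)
    S <- fac$H %*% t(fac$H)
    Sb <- fac$Hb %*% t(fac$Hb)
    proj <- rldaProjection(fac, lambda = 0)
    got <- rldaCriterion(proj$G, S, Sb, lambda = 0)
    want <- fisherOptOracle(S, Sb, proj$l)
    expect_lt(abs(got - want) / want, 1e-8)
    expect_lte(proj$l, s$nRegions - 1)
  }
})

test_that("two classes give a one-dimensional projection", {
  proj <- rldaProjection(scatterFactors(randomSample(12, 25, 2, seed = 9)))
  expect_equal(proj$l, 1)
  expect_equal(ncol(proj$G), 1)
})

test_that("the Fisher criterion decreases as lambda grows", {
  s <- randomSample(10, 50, 3, seed = 21)
  fac <- scatterFactors(s)
  S <- fac$H %*% t(fac$H)
  Sb <- fac$Hb %*% t(fac$Hb)
  vals <- vapply(c(0, 1, 1e3, 1e6), function(lam)
    rldaCriterion(rldaProjection(fac, lambda = lam)$G, S, Sb, lambda = 0),
    numeric(1))
  expect_true(all(diff(vals) <= 1e-10))
  expect_lt(vals[4], vals[1])
})

test_that("no random competitor beats the returned projection", {
  s <- randomSample(8, 30, 3, seed = 33)
  fac <- scatterFactors(s)
  S <- fac$H %*% t(fac$H)
  Sb <- fac$Hb %*% t(fac$Hb)
  proj <- rldaProjection(fac, lambda = 0)
  best <- rldaCriterion(proj$G, S, Sb)
  set.seed(1)
  for (i in 1:100) {
    G <- matrix(rnorm(8 * proj$l), 8)
    expect_lte(rldaCriterion(G, S, Sb), best + 1e-9)
  }
})

test_that("projection is invariant to pixel order within a region", {
  set.seed(17)
  X0 <- matrix(rnorm(6 * 12), 6) + rep(c(0, 3, 6), each = 4 * 6)
  cube <- HyperCube(array(X0, c(6, 3, 4)))
  mask <- LabelMask(matrix(rep(1:3, each = 4), 3, 4, byrow = TRUE))
  p1 <- rldaProjection(scatterFactors(buildMarkedSample(cube, mask)))
  # permute pixels inside each row (same regions, different order)
  perm <- c(3, 1, 4, 2)
  cube2 <- HyperCube(cube@data[, , perm])
  p2 <- rldaProjection(scatterFactors(buildMarkedSample(cube2, mask)))
  expect_equal(p1$G, p2$G, tolerance = 1e-10)
})

test_that("degenerate and invalid inputs error cleanly", {
  cube <- HyperCube(array(1, c(3, 1, 4)))
  mask <- LabelMask(matrix(c(1, 1, 2, 2), 1))
  fac <- scatterFactors(buildMarkedSample(cube, mask))
  expect_error(rldaProjection(fac), "degenerate")
  expect_error(rldaProjection(scatterFactors(randomSample(4, 10, 2, 1)),
                              lambda = -1), "nonnegative")
})

test_that("projectCube applies the linear map pixelwise", {
  set.seed(2)
  arr <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  cube <- HyperCube(arr)
  # permutation projection permutes the band planes
  P <- diag(4)[, c(3, 1, 4, 2)]
  Y <- projectCube(cube, list(G = P, l = 4))
  expect_equal(featureMatrix(Y), pixelMatrix(cube)[c(3, 1, 4, 2), ])
  # single pixel: explicit dot products
  G <- matrix(rnorm(8), 4, 2)
  Y2 <- projectCube(cube, list(G = G, l = 2))
  p <- 7  # pixel (2, 2): r=2, c=2 -> p = 1*5 + 2
  want <- c(sum(G[, 1] * arr[, 2, 2]), sum(G[, 2] * arr[, 2, 2]))
  expect_lt(max(abs(featureMatrix(Y2)[, p] - want)), 1e-12)
  # zero cube maps to zero; band mismatch errors
  expect_true(all(featureMatrix(
    projectCube(HyperCube(array(0, c(4, 2, 2))), list(G = G, l = 2))) == 0))
  expect_error(projectCube(HyperCube(array(1, c(3, 2, 2))),
                           list(G = G, l = 2)), "bands")
})
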