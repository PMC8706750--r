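# Independent oracles the implementation is checked against.  These are
# deliberately naive (dense algebra, explicit loops) and share no code with
# the package internals.

# Hitting probabilities of the absorbing Markov chain on a weighted graph:
# from the Laplacian, recover the adjacency, form the transition matrix,
# absorb at the seeds, and invert (I - Q) densely.
chainOracle <- function(L, lab) {
  Ld <- as.matrix(L)
  W <- diag(diag(Ld)) - Ld
  n <- nrow(W)
  P <- W / rowSums(W)
  m <- which(lab > 0)
  u <- which(lab == 0)
  nM <- max(lab)
  X <- matrix(0, n, nM)
  X[cbind(m, lab[m])] <- 1
  if (length(u)) {
    Q <- P[u, u, drop = FALSE]
    Rm <- P[u, m, drop = FALSE]
    hit <- solve(diag(length(u)) - Q, Rm)       # u x marked
    for (k in seq_len(nM)) X[u, k] <- hit %*% as.numeric(lab[m] == k)
  }
  X
}

# Sum of the top-l generalized eigenvalues of (Sb, S) restricted to
# range(S): the optimum of the classical Fisher trace criterion.
fisherOptOracle <- function(S, Sb, l) {
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  tol <- nrow(S) * .Machine$double.eps * max(es$values)
  keep <- es$values > tol
  T <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  M <- crossprod(T, Sb %*% T)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(ev[seq_len(l)])
}

# All-pairs brute-force Rand index over ground-truth-labeled pixels.
bruteRandIndex <- function(gt, seg) {
  keep <- gt > 0
  g <- gt[keep]; s <- seg[keep]
  n <- length(g)
  agree <- 0L
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      agree <- agree + ((g[i] == g[j]) == (s[i] == s[j]))
  agree / choose(n, 2)
}

# Row-max / column-max contingency oracles for OA and purity.
oaOracle <- function(gt, seg) {
  keep <- gt > 0
  g <- gt[keep]; s <- seg[keep]
  tot <- 0
  for (gi in unique(g)) {
    best <- 0
    for (sj in unique(s)) best <- max(best, sum(g == gi & s == sj))
    tot <- tot + best
  }
  tot / length(g)
}

purityOracle <- function(gt, seg) {
  keep <- gt > 0
  g <- gt[keep]; s <- seg[keep]
  tot <- 0
  for (sj in unique(s)) {
    best <- 0
    for (gi in unique(g)) best <- max(best, sum(g == gi & s == sj))
    tot <- tot + best
  }
  tot / length(g)
}

# A random lattice PixelGraph with its seed mask: random feature image,
# random connectivity, at least one seed per label.
randomLattice <- function(maxPixels = 64, nLabels = 2) {
  repeat {
    R <- sample(2:8, 1)
    C <- sample(2:8, 1)
    if (R * C <= maxPixels && R * C >= nLabels + 1) break
  }
  Y <- FeatureImage(matrix(rnorm(2 * R * C), 2), c(R, C))
  F <- patchFeatures(Y)
  g <- buildPixelGraph(F, connectivity = sample(c(4L, 8L), 1),
                       epsilon = 1e-3)
  lab <- integer(R * C)
  seedPx <- sample(R * C, nLabels)
  lab[seedPx] <- seq_len(nLabels)
  mask <- LabelMask(matrix(lab, R, C, byrow = TRUE))
  list(graph = g, mask = mask, dims = c(R, C))
}

# Small two-class scene with deterministic interior seeds (one 3x3 square
# centered in each stripe), for quick pipeline checks.  Interior placement
# keeps the class centroids free of cross-boundary patches, which is what
# makes noiseless recovery exact.
quickScene <- function(seed = 1, noise = "none", sigma = 0) {
  sc <- makeScene(rows = 14, cols = 14, bands = 10, classes = 2,
                  layout = "stripes", noise = noise, sigma = sigma,
                  seed = seed)
  m <- matrix(0L, 14, 14)
  m[6:8, 3:5] <- 1L    # stripe 1 spans cols 1..7
  m[6:8, 10:12] <- 2L  # stripe 2 spans cols 8..14
  c(sc, list(seeds = LabelMask(m)))
}
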