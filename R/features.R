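# window offsets scanned row-major (drow outer, dcol inner), center optional
.windowOffsets <- function(window, includeCenter) {
  h <- (window - 1L) %/% 2L
  off <- expand.grid(dc = -h:h, dr = -h:h)[, c("dr", "dc")]
  if (!includeCenter) off <- off[!(off$dr == 0L & off$dc == 0L), ]
  off
}

#' Stack neighborhood features per pixel
#'
#' For every pixel, gathers the l feature values of each pixel in its
#' `window x window` neighborhood (the center itself excluded by default,
#' so `Nb = window^2 - 1`, e.g. the 8-neighborhood for `window = 3`) into a
#' single stacked vector of length `l * Nb`.  Patches at the image border
#' are completed by replicate (edge-clamp) padding.  The stacking order is
#' fixed: offsets row-major over the window, feature index fastest.
#'
#' These stacked vectors carry the spatial context that the similarity
#' index and the random-walker edge weights are computed from.
#'
#' @param Y a [FeatureImage-class].
#' @param window odd neighborhood side (default 3).
#' @param includeCenter include the center pixel itself (default `FALSE`).
#' @return A [PatchFeatureSet-class] with `l * Nb` rows.
#' @examples
#' Y <- FeatureImage(matrix(seq_len(2 * 12), 2), c(3, 4))
#' f <- patchFeatures(Y)
#' nrow(featureMatrix(f))   # 2 features x 8 neighbors = 16
#' @export
patchFeatures <- function(Y, window = 3L, includeCenter = FALSE) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    .stopf("window must be an odd integer >= 1, got %d", window)
  dims <- spatialShape(Y)
  R <- dims[1L]; C <- dims[2L]
  off <- .windowOffsets(window, includeCenter)
  Nb <- nrow(off)
  l <- nrow(Y@values)
  co <- .pixelCoords(dims)
  F <- matrix(0, l * Nb, R * C)
  for (b in seq_len(Nb)) {
    rr <- pmin.int(pmax.int(co$r + off$dr[b], 1L), R)
    cc <- pmin.int(pmax.int(co$c + off$dc[b], 1L), C)
    F[(b - 1L) * l + seq_len(l), ] <- Y@values[, .pixelIndex(rr, cc, C)]
  }
  new("PatchFeatureSet", values = F, window = window,
      includeCenter = includeCenter, nFeatures = as.integer(l),
      dim = as.integer(dims))
}

#' Distance between two stacked feature vectors
#'
#' Euclidean by default; this is the distance `d` the similarity index
#' `1 / (d + epsilon)` is built on.
#'
#' @param fa,fb numeric vectors of equal length.
#' @param metric currently only `"euclidean"`.
#' @return A nonnegative scalar.
#' @export
featureDistance <- function(fa, fb, metric = c("euclidean")) {
  match.arg(metric)
  if (length(fa) != length(fb))
    .stopf("feature vectors differ in length (%d vs %d)",
           length(fa), length(fb))
  sqrt(sum((fa - fb)^2))
}

#' Similarity index between two stacked feature vectors
#'
#' `1 / (d(fa, fb) + epsilon)`: strictly decreasing in the distance, with
#' maximum `1 / epsilon` at distance zero.  The regularizer `epsilon`
#' (default 1e-3) keeps the index finite for identical patches.
#'
#' @param fa,fb numeric vectors of equal length.
#' @param epsilon positive regularizer.
#' @return A positive scalar in `(0, 1/epsilon]`.
#' @export
similarityIndex <- function(fa, fb, epsilon = 1e-3) {
  if (epsilon <= 0) .stopf("epsilon must be positive")
  1 / (featureDistance(fa, fb) + epsilon)
}

#' Per-class centroid patch features
#'
#' The centroid of class k is the arithmetic mean of the stacked feature
#' vectors of the pixels marked k - the starting centroids a k-means run
#' seeded on the marked regions would use.
#'
#' @param F a [PatchFeatureSet-class].
#' @param mask a [LabelMask-class] of seeds.
#' @return numeric matrix `(l * Nb, nM)`, one centroid per class.
#' @export
classCentroids <- function(F, mask) {
  if (!all(spatialShape(F) == spatialShape(mask)))
    .stopf("mask shape does not match the feature set")
  lab <- labelVector(mask)
  nM <- nRegions(mask)
  cents <- vapply(seq_len(nM), function(k) {
    i <- which(lab == k)
    if (!length(i)) .stopf("marked region %d contains no pixels", k)
    rowMeans(F@values[, i, drop = FALSE])
  }, numeric(nrow(F@values)))
  cents
}

#' Similarity of every pixel to every seed class
#'
#' `S[i, k] = 1 / (d(f_i, centroid_k) + epsilon)`: the "fidelity" half of
#' the final labeling rule.
#'
#' @param F a [PatchFeatureSet-class].
#' @param centroids matrix from [classCentroids()].
#' @param epsilon positive regularizer (default 1e-3).
#' @return numeric matrix `(nP, nM)` of positive similarities.
#' @export
similarityToLabels <- function(F, centroids, epsilon = 1e-3) {
  if (epsilon <= 0) .stopf("epsilon must be positive")
  if (nrow(centroids) != nrow(F@values))
    .stopf("centroid dimension (%d) does not match features (%d)",
           nrow(centroids), nrow(F@values))
  nP <- ncol(F@values)
  S <- matrix(0, nP, ncol(centroids))
  for (k in seq_len(ncol(centroids))) {
    d2 <- colSums((F@values - centroids[, k])^2)
    S[, k] <- 1 / (sqrt(pmax(d2, 0)) + epsilon)
  }
  S
}
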