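#' Collect the marked-pixel sample
#'
#' Extracts the spectra of all seed pixels from the cube, grouped by marked
#' region, together with the per-region sizes and means and the global mean.
#' This is the training sample the discriminant projection is fitted on.
#'
#' @param cube a [HyperCube-class].
#' @param mask a [LabelMask-class] of seeds on the same grid.
#' @return A list with components `X` (m x N_T spectra, columns grouped by
#'   region), `group` (region label of each column), `sizes` (n_j),
#'   `means` (m x nM region means), `mean` (global mean), `nRegions`.
#' @seealso [scatterFactors()]
#' @export
buildMarkedSample <- function(cube, mask) {
  if (!all(spatialShape(cube) == spatialShape(mask)))
    .stopf("mask shape (%s) does not match cube (%s)",
           paste(spatialShape(mask), collapse = "x"),
           paste(spatialShape(cube), collapse = "x"))
  X0 <- pixelMatrix(cube)
  lab <- labelVector(mask)
  nM <- nRegions(mask)
  if (nM < 2L) .stopf("at least 2 marked regions are required")
  idx <- lapply(seq_len(nM), function(k) which(lab == k))
  sizes <- lengths(idx)
  if (any(sizes == 0L))
    .stopf("marked region(s) %s contain no pixels",
           paste(which(sizes == 0L), collapse = ", "))
  cols <- unlist(idx)
  X <- X0[, cols, drop = FALSE]
  means <- vapply(idx, function(i) rowMeans(X0[, i, drop = FALSE]),
                  numeric(nrow(X0)))
  list(X = X,
       group = rep.int(seq_len(nM), sizes),
       sizes = sizes,
       means = means,
       mean = rowMeans(X),
       nRegions = nM)
}

#' Normalized scatter factor matrices
#'
#' Builds the factors `H` and `H_b` whose Gram products are the total and
#' between-class scatter matrices of the marked sample:
#' `H = (X_T - mu 1^T) / sqrt(N_T)` so `S = H H^T`, and column j of `H_b`
#' is `sqrt(n_j / N_T) (mu_j - mu)` so `S_b = H_b H_b^T`.  These are the
#' standard Fisher scalings, under which the efficient SVD algorithm below
#' reproduces the classical LDA solution at `lambda = 0`.
#'
#' @param sample output of [buildMarkedSample()].
#' @return A list with matrices `H` (m x N_T) and `Hb` (m x nM).
#' @export
scatterFactors <- function(sample) {
  NT <- ncol(sample$X)
  H <- (sample$X - sample$mean) / sqrt(NT)
  Hb <- (sample$means - sample$mean) *
    rep(sqrt(sample$sizes / NT), each = nrow(sample$means))
  list(H = H, Hb = Hb)
}

#' Regularized LDA projection (efficient two-SVD algorithm)
#'
#' Computes the projection `G` maximizing the regularized Fisher criterion
#' `trace((G^T (S + lambda I) G)^{-1} G^T S_b G)` without ever forming the
#' m x m scatter matrices: with the thin SVD `H = U D V^T` and numerical
#' rank r, set `D_s = D_r^2 + lambda I` and take the left singular vectors
#' `U_b` of `D_s^{-1/2} U_r^T H_b`; then `G = U_r D_s^{-1/2} U_b`, truncated
#' to the l columns with nonzero singular values (so `l <= nM - 1`).  At
#' `lambda = 0` this is classical LDA restricted to the range of the data.
#'
#' Numerical rank uses the tolerance `rankTol * max(dim) * eps * sigma_max`;
#' column signs are fixed by making each column's largest-magnitude entry
#' positive, so the output is reproducible and invariant to the ordering of
#' marked pixels within a region.
#'
#' @param factors output of [scatterFactors()].
#' @param lambda nonnegative ridge on the total scatter (default 0.01).
#' @param lMax optional cap on the retained dimension l.
#' @param rankTol multiplier on the default rank tolerance (default 1).
#' @return A list with `G` (m x l), `l`, `lambda` and the singular values
#'   `d` of `H` and `db` of the second SVD.
#' @examples
#' set.seed(1)
#' X <- cbind(matrix(rnorm(40, 0), 4), matrix(rnorm(40, 3), 4))
#' cube <- HyperCube(array(X, c(4, 4, 5)))
#' mask <- LabelMask(matrix(c(rep(1, 10), rep(2, 10)), 4, 5, byrow = TRUE))
#' fac <- scatterFactors(buildMarkedSample(cube, mask))
#' rldaProjection(fac, lambda = 0.01)$l   # two classes -> l = 1
#' @export
rldaProjection <- function(factors, lambda = 0.01, lMax = Inf, rankTol = 1) {
  if (lambda < 0) .stopf("lambda must be nonnegative")
  H <- factors$H; Hb <- factors$Hb
  if (all(H == 0))
    .stopf("degenerate input: the centered marked sample is identically zero")
  sv <- svd(H)
  tol <- rankTol * max(dim(H)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  U <- sv$u[, seq_len(r), drop = FALSE]
  dsInv <- 1 / sqrt(sv$d[seq_len(r)]^2 + lambda)
  M <- dsInv * crossprod(U, Hb)
  svb <- svd(M)
  tolb <- rankTol * max(dim(M)) * .Machine$double.eps * max(svb$d, 0)
  l <- sum(svb$d > tolb)
  if (l == 0L)
    .stopf("degenerate input: no between-class separation in the marked sample")
  # rank(H_b) <= nM - 1 holds exactly (its sqrt(n_j)-weighted columns sum
  # to zero), but the D_s^{-1/2} scaling can lift the trailing numerical
  # zero past the relative tolerance; cap explicitly
  if (ncol(Hb) >= 2L) l <- min(l, ncol(Hb) - 1L)
  l <- min(l, lMax)
  G <- U %*% (dsInv * svb$u[, seq_len(l), drop = FALSE])
  # fix column signs for reproducibility
  for (j in seq_len(ncol(G))) {
    i <- which.max(abs(G[, j]))
    if (G[i, j] < 0) G[, j] <- -G[, j]
  }
  list(G = G, l = l, lambda = lambda, d = sv$d, db = svb$d)
}

#' Evaluate the (regularized) Fisher trace criterion
#'
#' `trace((G^T (S + lambda I) G)^{-1} G^T S_b G)` for a candidate projection
#' `G` and scatter matrices `S`, `Sb`.  Used to compare projections; the
#' RLDA solution maximizes it over m x l matrices.
#'
#' @param G candidate projection (m x l).
#' @param S total scatter matrix (m x m).
#' @param Sb between-class scatter matrix (m x m).
#' @param lambda ridge parameter.
#' @return The criterion value (a scalar).
#' @export
rldaCriterion <- function(G, S, Sb, lambda = 0) {
  A <- crossprod(G, (S + diag(lambda, nrow(S))) %*% G)
  B <- crossprod(G, Sb %*% G)
  sum(diag(solve(A, B)))
}

#' Project the full cube to the feature image
#'
#' Maps every pixel spectrum through the discriminant projection:
#' `Y = G^T X0`, preserving the spatial shape.
#'
#' @param cube a [HyperCube-class].
#' @param projection output of [rldaProjection()].
#' @return A [FeatureImage-class] with `l` features per pixel.
#' @export
projectCube <- function(cube, projection) {
  if (nrow(projection$G) != nBands(cube))
    .stopf("projection expects %d bands, cube has %d",
           nrow(projection$G), nBands(cube))
  FeatureImage(crossprod(projection$G, pixelMatrix(cube)),
               spatialShape(cube))
}
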