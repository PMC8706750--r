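#' Build the similarity-weighted pixel graph
#'
#' One vertex per pixel; edges join 4- or 8-neighboring pixel pairs, each
#' weighted by the similarity index `1 / (d(f_i, f_j) + epsilon)` between
#' the endpoints' stacked patch features.  Strong similarity (small patch
#' distance) gives a heavy edge, so a random walker preferentially stays
#' within homogeneous regions.
#'
#' @param F a [PatchFeatureSet-class].
#' @param connectivity 4 (default) or 8.
#' @param epsilon positive regularizer of the similarity (default 1e-3).
#' @param beta if non-`NULL`, use the exponential weight
#'   `exp(-beta * d^2)` instead of the inverse-distance similarity.
#' @return A [PixelGraph-class].
#' @export
buildPixelGraph <- function(F, connectivity = 4L, epsilon = 1e-3,
                            beta = NULL) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) .stopf("connectivity must be 4 or 8")
  if (epsilon <= 0) .stopf("epsilon must be positive")
  dims <- spatialShape(F)
  R <- dims[1L]; C <- dims[2L]
  if (R * C < 2L) .stopf("the graph needs at least two pixels")
  co <- .pixelCoords(dims)
  dirs <- list(c(0L, 1L), c(1L, 0L))              # right, down
  if (connectivity == 8L)
    dirs <- c(dirs, list(c(1L, 1L), c(1L, -1L)))  # down-right, down-left
  ei <- integer(0); ej <- integer(0)
  for (d in dirs) {
    ok <- co$r + d[1L] >= 1L & co$r + d[1L] <= R &
          co$c + d[2L] >= 1L & co$c + d[2L] <= C
    i <- which(ok)
    j <- .pixelIndex(co$r[i] + d[1L], co$c[i] + d[2L], C)
    ei <- c(ei, i); ej <- c(ej, j)
  }
  d2 <- colSums((F@values[, ei, drop = FALSE] -
                 F@values[, ej, drop = FALSE])^2)
  w <- if (is.null(beta)) 1 / (sqrt(pmax(d2, 0)) + epsilon)
       else exp(-beta * d2)
  swap <- ei > ej
  edges <- cbind(ifelse(swap, ej, ei), ifelse(swap, ei, ej))
  storage.mode(edges) <- "integer"
  new("PixelGraph", edges = edges, weights = as.numeric(w),
      nVertices = as.integer(R * C), connectivity = connectivity,
      dim = as.integer(dims))
}

#' Graph Laplacian of a pixel graph
#'
#' `L[i, i]` is the weighted degree of vertex i, `L[i, j] = -w(i, j)` for
#' adjacent pairs, 0 otherwise.  `L` is symmetric positive semi-definite
#' with zero row sums; its quadratic form is the Dirichlet energy
#' `E(x) = x^T L x / 2` the random walker minimizes.
#'
#' @param graph a [PixelGraph-class].
#' @return A symmetric sparse `Matrix::dsCMatrix`.
#' @export
graphLaplacian <- function(graph) {
  n <- graph@nVertices
  W <- Matrix::sparseMatrix(i = graph@edges[, 1L], j = graph@edges[, 2L],
                            x = graph@weights, dims = c(n, n),
                            symmetric = TRUE)
  Matrix::forceSymmetric(Matrix::Diagonal(x = Matrix::colSums(W)) - W)
}

# connected components of the graph underlying a Laplacian
.laplacianComponents <- function(L) {
  T <- methods::as(methods::as(L, "generalMatrix"), "TsparseMatrix")
  off <- T@i != T@j
  g <- igraph::graph_from_edgelist(cbind(T@i[off] + 1L, T@j[off] + 1L),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(L) - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Solve the seeded random-walker Dirichlet problem
#'
#' Splits the vertices into marked (seed) and unmarked sets.  Seed rows of
#' the probability matrix are one-hot in their label; the unmarked block
#' solves the sparse symmetric positive-definite system
#' `L_u X_u = -B^T X_m` (one right-hand side per label), where `L_u` and
#' `B` are the unmarked diagonal block and the marked/unmarked off-diagonal
#' block of the Laplacian.  Equivalently, `X[i, k]` is the probability that
#' a random walk from pixel i first hits a seed of label k; rows sum to 1.
#'
#' The system is nonsingular iff every connected component of the graph
#' contains a seed; components without one raise an error naming them.
#' Entries outside `[0, 1]` by more than `clipTol` raise an error
#' (solver failure); smaller violations are clipped as roundoff.
#'
#' @param L Laplacian from [graphLaplacian()].
#' @param mask a [LabelMask-class] of seeds (flattened row-major to match
#'   the pixel order of the graph).
#' @param clipTol roundoff tolerance for clipping (default 1e-8).
#' @return A [ProbabilityField-class].
#' @examples
#' Y <- FeatureImage(matrix(0, 1, 3), c(1, 3))
#' F <- patchFeatures(Y)
#' g <- buildPixelGraph(F)
#' mask <- LabelMask(matrix(c(1L, 0L, 2L), 1))
#' probabilityMatrix(solveDirichlet(graphLaplacian(g), mask))[2, ]  # 0.5 0.5
#' @export
solveDirichlet <- function(L, mask, clipTol = 1e-8) {
  lab <- labelVector(mask)
  if (length(lab) != nrow(L))
    .stopf("mask has %d pixels, Laplacian %d vertices", length(lab), nrow(L))
  nM <- nRegions(mask)
  if (nM < 2L) .stopf("at least 2 seed labels are required")
  mIdx <- which(lab > 0L)
  uIdx <- which(lab == 0L)
  comp <- .laplacianComponents(L)
  seedless <- setdiff(unique(comp), unique(comp[mIdx]))
  if (length(seedless))
    .stopf("connected component(s) without any seed: %s (sizes %s)",
           paste(seedless, collapse = ", "),
           paste(tabulate(comp)[seedless], collapse = ", "))
  Xm <- matrix(0, length(mIdx), nM)
  Xm[cbind(seq_along(mIdx), lab[mIdx])] <- 1
  X <- matrix(0, length(lab), nM)
  X[mIdx, ] <- Xm
  if (length(uIdx)) {
    Lu <- Matrix::forceSymmetric(L[uIdx, uIdx, drop = FALSE])
    rhs <- -L[uIdx, mIdx, drop = FALSE] %*% Xm
    Xu <- as.matrix(Matrix::solve(Lu, rhs))
    bad <- max(0, max(-Xu), max(Xu - 1))
    if (bad > clipTol)
      .stopf("Dirichlet solve outside [0,1] by %.3g: solver failure", bad)
    X[uIdx, ] <- pmin(pmax(Xu, 0), 1)
  }
  new("ProbabilityField", probs = X, dim = as.integer(spatialShape(mask)))
}

#' Dirichlet energy of a labeling vector
#'
#' `E(x) = sum over edges of w_ij (x_i - x_j)^2 / 2 = x^T L x / 2`; the
#' random-walker probabilities minimize it per label subject to the seed
#' values.
#'
#' @param graph a [PixelGraph-class].
#' @param x numeric vector over the vertices.
#' @return The energy (scalar).
#' @export
dirichletEnergy <- function(graph, x) {
  dif <- x[graph@edges[, 1L]] - x[graph@edges[, 2L]]
  sum(graph@weights * dif^2) / 2
}
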