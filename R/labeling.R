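#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full segmentation pipeline.
#'
#' * `alpha` in `[0, 1]` weighs the similarity term against the
#'   random-walker term in the final labeling: `alpha = 1` is pure
#'   nearest-centroid similarity, `alpha = 0` the pure seeded random
#'   walker; the default 0.8 leans on similarity while letting the walker
#'   regularize.
#' * `lambda >= 0` is the ridge of the discriminant projection
#'   (default 0.01).
#' * `epsilon > 0` regularizes the similarity index (default 1e-3).
#' * `window`/`includeCenter` define the patch neighborhood (default 3x3
#'   with the center excluded, i.e. the 8-neighborhood).
#' * `connectivity` of the pixel graph: 4 (default) or 8.
#' * `pMin` floors the walker probabilities before taking logs
#'   (default 1e-12).
#' * `lMax` optionally caps the projected dimension.
#'
#' @param alpha,lambda,epsilon,window,includeCenter,connectivity,pMin,lMax
#'   see above.
#' @return A list of class `"hsPipelineConfig"`.
#' @export
pipelineConfig <- function(alpha = 0.8, lambda = 0.01, epsilon = 1e-3,
                           window = 3L, includeCenter = FALSE,
                           connectivity = 4L, pMin = 1e-12, lMax = Inf) {
  if (alpha < 0 || alpha > 1) .stopf("alpha must lie in [0, 1]")
  if (lambda < 0) .stopf("lambda must be nonnegative")
  if (epsilon <= 0) .stopf("epsilon must be positive")
  if (pMin <= 0) .stopf("pMin must be positive")
  structure(list(alpha = alpha, lambda = lambda, epsilon = epsilon,
                 window = as.integer(window), includeCenter = includeCenter,
                 connectivity = as.integer(connectivity), pMin = pMin,
                 lMax = lMax),
            class = "hsPipelineConfig")
}

#' Final labeling: convex log-combination of similarity and walker
#'
#' Each unmarked pixel gets the label maximizing
#' `alpha * log S[i, k] + (1 - alpha) * log x[i, k]`, equivalently (by
#' monotonicity of the log on positive scores) the label maximizing
#' `S^alpha * x^(1 - alpha)`.  Walker probabilities are floored at `pMin`
#' before the log so that exact zeros (seeds of other labels) stay finite.
#' Marked pixels bypass the rule and keep their seed label.  Ties break
#' toward the smallest label index.
#'
#' @param S similarity matrix from [similarityToLabels()] (`nP x nM`,
#'   positive).
#' @param prob a [ProbabilityField-class].
#' @param mask the seed [LabelMask-class].
#' @param alpha convex weight in `[0, 1]`.
#' @param pMin positive probability floor (default 1e-12).
#' @return A [SegmentationMap-class].
#' @export
combineLabels <- function(S, prob, mask, alpha = 0.8, pMin = 1e-12) {
  if (alpha < 0 || alpha > 1) .stopf("alpha must lie in [0, 1]")
  X <- probabilityMatrix(prob)
  if (!all(dim(S) == dim(X)))
    .stopf("similarity (%dx%d) and probabilities (%dx%d) disagree",
           nrow(S), ncol(S), nrow(X), ncol(X))
  if (any(S <= 0)) .stopf("similarities must be strictly positive")
  score <- alpha * log(S) + (1 - alpha) * log(pmax(X, pMin))
  lab <- max.col(score, ties.method = "first")
  seed <- labelVector(mask)
  lab[seed > 0L] <- seed[seed > 0L]
  SegmentationMap(.unflattenRowMajor(lab, spatialShape(mask)))
}

#' Run the full segmentation pipeline
#'
#' Executes, in order: marked-sample extraction, scatter factorization,
#' regularized discriminant projection, cube projection, patch feature
#' stacking, class centroids, similarity to labels, pixel-graph assembly,
#' Laplacian, seeded random-walker Dirichlet solve, and the final convex
#' log-combination labeling.  Errors are tagged with the stage they arose
#' in.
#'
#' @param cube a [HyperCube-class].
#' @param mask a seed [LabelMask-class] (labels `1..nM`, 0 elsewhere).
#' @param config a [pipelineConfig()].
#' @param verbose print per-stage dimensions and timings.
#' @return A list with `segmentation` ([SegmentationMap-class]),
#'   `probability` ([ProbabilityField-class]), `similarity` (`nP x nM`
#'   matrix), `projection` (from [rldaProjection()]) and `features`
#'   (the [PatchFeatureSet-class]).
#' @examples
#' sc <- makeScene(rows = 12, cols = 12, bands = 8, classes = 2,
#'                 layout = "stripes", seed = 1)
#' seeds <- makeSeeds(sc$truth, squaresPerClass = 1, squareSide = 3, seed = 2)
#' res <- runPipeline(sc$cube, seeds)
#' overallAccuracy(sc$truth, res$segmentation)
#' @export
runPipeline <- function(cube, mask, config = pipelineConfig(),
                        verbose = FALSE) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      .stopf("[stage %s] %s", name, conditionMessage(e)))
    if (verbose)
      message(sprintf("  stage %-18s %6.2fs", name,
                      proc.time()[["elapsed"]] - t0))
    out
  }
  sample <- stage("marked_sample", buildMarkedSample(cube, mask))
  fac    <- stage("scatter_factors", scatterFactors(sample))
  proj   <- stage("rlda_projection",
                  rldaProjection(fac, lambda = config$lambda,
                                 lMax = config$lMax))
  Y      <- stage("project_cube", projectCube(cube, proj))
  F      <- stage("patch_features",
                  patchFeatures(Y, window = config$window,
                                includeCenter = config$includeCenter))
  cents  <- stage("class_centroids", classCentroids(F, mask))
  S      <- stage("similarity_to_labels",
                  similarityToLabels(F, cents, epsilon = config$epsilon))
  graph  <- stage("build_graph",
                  buildPixelGraph(F, connectivity = config$connectivity,
                                  epsilon = config$epsilon))
  L      <- stage("laplacian", graphLaplacian(graph))
  prob   <- stage("solve_dirichlet", solveDirichlet(L, mask))
  seg    <- stage("combine_labels",
                  combineLabels(S, prob, mask, alpha = config$alpha,
                                pMin = config$pMin))
  if (verbose)
    message(sprintf(
      "  dims: m = %d, l = %d, Nb = %d, nP = %d, nM = %d",
      nBands(cube), proj$l, nrow(F@values) / F@nFeatures,
      nPixels(cube), nRegions(mask)))
  list(segmentation = seg, probability = prob, similarity = S,
       projection = proj, features = F)
}
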