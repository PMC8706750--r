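#' Random class spectral signatures with controlled separation
#'
#' Draws one signature per class (smooth random bump mixtures) and rescales
#' the deviations about their common mean so that the minimum pairwise
#' Euclidean distance equals `separation`, then shifts all signatures by a
#' common offset so every value is at least `floor` (shifting preserves the
#' pairwise distances and keeps Poisson intensities valid).  Quoting noise
#' levels relative to `separation` makes scene difficulty scale-free.
#'
#' @param bands number of spectral bands m.
#' @param classes number of classes g.
#' @param separation target minimum pairwise Euclidean distance.
#' @param floor minimum signature value after shifting (default 0.05 *
#'   `separation / sqrt(bands)`).
#' @param seed optional RNG seed.
#' @return numeric matrix `(bands, classes)` of nonnegative signatures,
#'   pairwise distinct.
#' @export
makeSignatures <- function(bands, classes, separation = 1,
                           floor = 0.05 * separation / sqrt(bands),
                           seed = NULL) {
  if (classes < 1) .stopf("at least one class is required")
  .withSeed(seed, {
    x <- seq(0, 1, length.out = bands)
    sig <- vapply(seq_len(classes), function(k) {
      centers <- stats::runif(3); widths <- stats::runif(3, 0.05, 0.3)
      amps <- stats::runif(3, 0.5, 1.5)
      colSums(amps * exp(-outer(centers, x, "-")^2 / (2 * widths^2)))
    }, numeric(bands))
    sig <- matrix(sig, bands, classes)
    if (classes > 1) {
      dmin <- min(stats::dist(t(sig)))
      if (dmin <= 0) .stopf("degenerate signature draw; change the seed")
      mu <- rowMeans(sig)
      sig <- mu + (sig - mu) * (separation / dmin)
    }
    sig + max(0, floor - min(sig))
  })
}

# class layout rasters ------------------------------------------------------

# exactly g rectangles, one connected region per class: rows are split into
# floor(sqrt(g)) horizontal bands and each band into a near-equal share of
# the g columns-of-blocks
.layoutBlocks <- function(R, C, g) {
  nbr <- max(1L, floor(sqrt(g)))
  perBand <- diff(round(seq(0, g, length.out = nbr + 1L)))
  br <- pmin(ceiling(seq_len(R) / (R / nbr)), nbr)
  lab <- matrix(0L, R, C)
  offset <- 0L
  for (i in seq_len(nbr)) {
    k <- perBand[i]
    bc <- pmin(ceiling(seq_len(C) / (C / k)), k)
    lab[br == i, ] <- matrix(rep(offset + bc, each = sum(br == i)),
                             sum(br == i), C)
    offset <- offset + k
  }
  lab
}

.layoutStripes <- function(R, C, g) {
  s <- pmin(ceiling(seq_len(C) / (C / g)), g)
  matrix(rep(s, each = R), R, C, byrow = FALSE)
}

.layoutVoronoi <- function(R, C, g) {
  ctr <- cbind(stats::runif(g, 1, R), stats::runif(g, 1, C))
  co <- .pixelCoords(c(R, C))
  d2 <- outer(co$r, ctr[, 1L], "-")^2 + outer(co$c, ctr[, 2L], "-")^2
  .unflattenRowMajor(max.col(-d2, ties.method = "first"), c(R, C))
}

#' Generate a synthetic hyperspectral scene with ground truth
#'
#' Emulates the structure of benchmark scenes: a set of approximately
#' homogeneous regions (piecewise-constant class signatures) observed under
#' additive Gaussian noise or signal-dependent Poisson noise.  Every
#' pixel's spectrum is its class signature plus noise; the ground truth
#' records each pixel's class.  Deterministic under a fixed seed.
#'
#' What this generator does not emulate: mixed pixels, spatially correlated
#' noise, atmospheric effects, and within-class spectral variability of
#' real sensors.
#'
#' @param rows,cols spatial shape.
#' @param bands number of spectral bands.
#' @param classes number of classes g.
#' @param layout `"blocks"` (grid of rectangles), `"stripes"` (vertical
#'   bands) or `"voronoi"` (random nearest-center cells; always yields g
#'   nonempty cells since each center pixel belongs to its own cell).
#' @param signatures optional `(bands, classes)` matrix; drawn by
#'   [makeSignatures()] when `NULL`.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param sigma Gaussian noise standard deviation per band (absolute units;
#'   quote it relative to the signature separation for a scale-free
#'   difficulty).
#' @param separation minimum pairwise signature distance when signatures
#'   are drawn here.
#' @param seed optional RNG seed; the layout, signatures and noise all
#'   derive from it.
#' @return A list with `cube` ([HyperCube-class]), `truth`
#'   ([LabelMask-class]) and `signatures`.
#' @export
makeScene <- function(rows, cols, bands, classes,
                      layout = c("blocks", "stripes", "voronoi"),
                      signatures = NULL,
                      noise = c("none", "gaussian", "poisson"),
                      sigma = 0, separation = 1, seed = NULL) {
  layout <- match.arg(layout)
  noise <- match.arg(noise)
  if (classes > rows * cols) .stopf("more classes than pixels")
  if (classes < 1) .stopf("at least one class is required")
  if (sigma < 0) .stopf("sigma must be nonnegative")
  if (is.null(signatures))
    signatures <- makeSignatures(bands, classes, separation = separation,
                                 seed = .splitSeed(seed, 1L))
  if (nrow(signatures) != bands || ncol(signatures) != classes)
    .stopf("signatures must be a (bands x classes) matrix")
  if (classes > 1 && min(stats::dist(t(signatures))) == 0)
    .stopf("signatures must be pairwise distinct")
  truth <- .withSeed(.splitSeed(seed, 2L), switch(layout,
    blocks  = .layoutBlocks(rows, cols, classes),
    stripes = .layoutStripes(rows, cols, classes),
    voronoi = .layoutVoronoi(rows, cols, classes)))
  if (length(unique(as.vector(truth))) < classes)
    .stopf("layout '%s' left some class empty; reduce classes", layout)
  lab <- .flattenRowMajor(truth)
  clean <- signatures[, lab, drop = FALSE]          # bands x nP
  data <- .withSeed(.splitSeed(seed, 3L), switch(noise,
    none = clean,
    gaussian = clean + stats::rnorm(length(clean), sd = sigma),
    poisson = {
      if (any(clean < 0)) .stopf("Poisson noise needs nonnegative signatures")
      matrix(stats::rpois(length(clean), clean), nrow(clean))
    }))
  arr <- aperm(array(data, c(bands, cols, rows)), c(1L, 3L, 2L))
  list(cube = HyperCube(arr), truth = LabelMask(truth),
       signatures = signatures)
}

#' Random square seed patches inside each class region
#'
#' For each ground-truth class, places `squaresPerClass` axis-aligned
#' squares of side `squareSide` with centers drawn uniformly among the
#' class's pixels, then clips each square to the image and intersects it
#' with the class's own region, so every marked pixel's seed label equals
#' its ground-truth label.
#'
#' @param truth ground-truth [LabelMask-class].
#' @param squaresPerClass squares per class (default 2).
#' @param squareSide square side in pixels (default 7).
#' @param seed optional RNG seed.
#' @return A seed [LabelMask-class].
#' @export
makeSeeds <- function(truth, squaresPerClass = 2L, squareSide = 7L,
                      seed = NULL) {
  if (squaresPerClass < 1L || squareSide < 1L)
    .stopf("squaresPerClass and squareSide must be positive")
  gt <- labelMatrix(truth)
  R <- nrow(gt); C <- ncol(gt)
  h <- (squareSide - 1L) %/% 2L
  seedMask <- matrix(0L, R, C)
  .withSeed(seed, {
    for (k in seq_len(nRegions(truth))) {
      px <- which(gt == k)                 # column-major indices into gt
      if (!length(px)) .stopf("class %d has an empty region", k)
      centers <- px[sample.int(length(px), squaresPerClass, replace = TRUE)]
      for (p in centers) {
        r0 <- ((p - 1L) %% R) + 1L
        c0 <- ((p - 1L) %/% R) + 1L
        rr <- max(1L, r0 - h):min(R, r0 - h + squareSide - 1L)
        cc <- max(1L, c0 - h):min(C, c0 - h + squareSide - 1L)
        sq <- gt[rr, cc, drop = FALSE] == k   # clip to the class region
        seedMask[rr, cc][sq] <- k
      }
    }
  })
  LabelMask(seedMask)
}

#' Fixed battery of scaled-down benchmark scenes
#'
#' A deterministic battery emulating the benchmark experiments at desk
#' scale, all randomness split from one seed:
#'
#' 1. `blocks-gaussian`: 64 x 64, 40 bands, 5 classes in blocks, additive
#'    Gaussian noise with per-band sigma at 5% of the signature
#'    separation;
#' 2. `blocks-poisson`: same structure with signal-dependent Poisson noise
#'    (signatures scaled to count level 1000);
#' 3. `voronoi-gaussian`: 80 x 80, 8 Voronoi classes, same relative
#'    Gaussian noise.
#'
#' Each entry carries the two-squares-of-side-7 seed protocol and an
#' expected overall-accuracy floor for the default pipeline settings
#' (`alpha = 0.8`, `lambda = 0.01`).
#'
#' @param seed integer master seed (default 1).
#' @return A list of entries `name`, `cube`, `truth`, `seeds`, `oaFloor`.
#' @export
makeBenchmarkSuite <- function(seed = 1L) {
  entry <- function(name, scene, seedSeed, oaFloor) {
    list(name = name, cube = scene$cube, truth = scene$truth,
         seeds = makeSeeds(scene$truth, squaresPerClass = 2L,
                           squareSide = 7L, seed = seedSeed),
         oaFloor = oaFloor)
  }
  s1 <- makeScene(64, 64, 40, 5, layout = "blocks", noise = "gaussian",
                  sigma = 0.05, separation = 1, seed = .splitSeed(seed, 11L))
  s2 <- makeScene(64, 64, 40, 5, layout = "blocks", noise = "poisson",
                  separation = 1000, seed = .splitSeed(seed, 12L))
  s3 <- makeScene(80, 80, 40, 8, layout = "voronoi", noise = "gaussian",
                  sigma = 0.05, separation = 1, seed = .splitSeed(seed, 13L))
  list(entry("blocks-gaussian", s1, .splitSeed(seed, 21L), 0.95),
       entry("blocks-poisson", s2, .splitSeed(seed, 22L), 0.95),
       entry("voronoi-gaussian", s3, .splitSeed(seed, 23L), 0.90))
}
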