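#' @import methods
NULL

#' HyperCube: an in-memory hyperspectral image
#'
#' Container for an m-band spectral image held in canonical
#' (band, row, col) order.  Pixels are linearized row-major into a single
#' index `p = (r - 1) * C + c`, `p = 1, ..., nP`; every per-pixel matrix in
#' the package (feature images, patch features, probabilities) uses this
#' pixel order for its columns or rows.
#'
#' @slot data numeric array of dimension `(bands, rows, cols)`; all values
#'   finite.
#' @slot wavelength optional per-band wavelengths in nm (length 0 or
#'   `nBands`).
#'
#' @seealso [loadCube()], [pixelMatrix()], [projectCube()]
#' @export
setClass("HyperCube",
  slots = c(data = "array", wavelength = "numeric"))

setValidity("HyperCube", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3-dimensional (band, row, col) array")
  if (!is.numeric(d))
    return("data must be numeric")
  if (dim(d)[1L] < 1L)
    return("at least one band is required")
  if (prod(dim(d)[2:3]) < 2L)
    return("the image must contain at least two pixels")
  if (!all(is.finite(d)))
    return("all cube values must be finite")
  wl <- object@wavelength
  if (length(wl) && length(wl) != dim(d)[1L])
    return("wavelength must have one entry per band")
  TRUE
})

#' Construct a HyperCube
#'
#' @param data 3-D numeric array in `(band, row, col)` order.
#' @param wavelength optional numeric vector of band wavelengths (nm).
#' @return A [HyperCube-class] object.
#' @examples
#' cube <- HyperCube(array(runif(4 * 5 * 6), c(4, 5, 6)))
#' nBands(cube)
#' @export
HyperCube <- function(data, wavelength = numeric()) {
  new("HyperCube", data = array(as.numeric(data), dim(data)),
      wavelength = as.numeric(wavelength))
}

#' LabelMask: integer region labels on the pixel grid
#'
#' A `(rows, cols)` integer raster with 0 marking unlabeled pixels and
#' values `1..nM` marking the labeled regions.  Used both for user seeds
#' (marked regions) and for ground-truth partitions.
#'
#' @slot labels integer matrix `(rows, cols)`, values in `{0, 1, ..., nM}`;
#'   every label `1..nM` occurs at least once.
#'
#' @seealso [loadMask()], [makeSeeds()]
#' @export
setClass("LabelMask", slots = c(labels = "matrix"))

setValidity("LabelMask", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be numeric")
  if (any(!is.finite(l)) || any(l != round(l)))
    return("labels must be finite integers")
  if (any(l < 0)) return("labels must be nonnegative")
  mx <- max(l)
  if (mx < 1) return("at least one labeled region is required")
  present <- unique(as.integer(l[l > 0]))
  missing <- setdiff(seq_len(mx), present)
  if (length(missing))
    return(sprintf("labels must be contiguous 1..nM; missing: %s",
                   paste(missing, collapse = ", ")))
  TRUE
})

#' Construct a LabelMask
#'
#' @param labels integer matrix `(rows, cols)`; 0 = unlabeled.
#' @return A [LabelMask-class] object.
#' @export
LabelMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels)
}

#' SegmentationMap: one label per pixel
#'
#' The final labeling: every pixel carries a label in `1..nM`; there are no
#' unlabeled pixels.  Seed pixels retain the label of their marked region.
#'
#' @slot labels integer matrix `(rows, cols)` with values in `1..nM`.
#' @seealso [combineLabels()], [runPipeline()]
#' @export
setClass("SegmentationMap", slots = c(labels = "matrix"))

setValidity("SegmentationMap", function(object) {
  l <- object@labels
  if (any(!is.finite(l)) || any(l != round(l)))
    return("labels must be finite integers")
  if (any(l < 1)) return("every pixel must carry a label >= 1")
  TRUE
})

#' @rdname SegmentationMap-class
#' @param labels integer matrix `(rows, cols)`, values >= 1.
#' @export
SegmentationMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("SegmentationMap", labels = labels)
}

#' FeatureImage: the projected (reduced-band) image
#'
#' Holds `Y = G^T X0`, the l-dimensional discriminant projection of the
#' spectral cube, one column per pixel in row-major pixel order.
#'
#' @slot values numeric matrix `(l, nP)`.
#' @slot dim integer spatial shape `(rows, cols)`.
#' @seealso [projectCube()], [patchFeatures()]
#' @export
setClass("FeatureImage", slots = c(values = "matrix", dim = "integer"))

setValidity("FeatureImage", function(object) {
  if (ncol(object@values) != prod(object@dim))
    return("one column per pixel is required")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' @rdname FeatureImage-class
#' @param values numeric matrix `(l, nP)`.
#' @param dim integer `(rows, cols)`.
#' @export
FeatureImage <- function(values, dim) {
  new("FeatureImage", values = values, dim = as.integer(dim))
}

#' PatchFeatureSet: stacked neighborhood features
#'
#' Column `p` stacks the l feature values of every neighbor of pixel `p`
#' within its window, neighbor-offset-major with the feature index running
#' fastest: rows `(b - 1) * l + (1:l)` hold the features of the b-th offset.
#' Offsets are scanned row-major over the window (`drow` outer, `dcol`
#' inner); the center offset is skipped unless `includeCenter`.  Borders use
#' replicate (edge-clamp) padding.
#'
#' @slot values numeric matrix `(l * Nb, nP)`.
#' @slot window odd window side.
#' @slot includeCenter logical; is the center pixel one of the neighbors?
#' @slot nFeatures the per-pixel feature dimension l.
#' @slot dim integer spatial shape `(rows, cols)`.
#' @seealso [patchFeatures()]
#' @export
setClass("PatchFeatureSet",
  slots = c(values = "matrix", window = "integer", includeCenter = "logical",
            nFeatures = "integer", dim = "integer"))

setValidity("PatchFeatureSet", function(object) {
  if (object@window < 1L || object@window %% 2L == 0L)
    return("window must be odd and >= 1")
  nb <- object@window^2L - (!object@includeCenter)
  if (nb < 1L) return("the neighborhood must contain at least one pixel")
  if (nrow(object@values) != object@nFeatures * nb)
    return("values must have l * Nb rows")
  if (ncol(object@values) != prod(object@dim))
    return("one column per pixel is required")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' PixelGraph: the similarity-weighted lattice graph
#'
#' Undirected graph on the pixels, one vertex per pixel, one edge per
#' neighboring pixel pair under 4- or 8-connectivity, stored once with
#' `edges[, 1] < edges[, 2]`.  Edge weights are the similarity index
#' `1 / (d + epsilon)` between the endpoints' patch features, so they are
#' strictly positive.
#'
#' @slot edges integer matrix `(nE, 2)` of pixel indices.
#' @slot weights positive edge weights.
#' @slot nVertices number of pixels.
#' @slot connectivity 4 or 8.
#' @slot dim integer spatial shape `(rows, cols)`.
#' @seealso [buildPixelGraph()], [graphLaplacian()]
#' @export
setClass("PixelGraph",
  slots = c(edges = "matrix", weights = "numeric", nVertices = "integer",
            connectivity = "integer", dim = "integer"))

setValidity("PixelGraph", function(object) {
  if (ncol(object@edges) != 2L) return("edges must have two columns")
  if (nrow(object@edges) != length(object@weights))
    return("one weight per edge is required")
  if (any(object@weights <= 0)) return("all weights must be positive")
  if (any(object@edges < 1L) || any(object@edges > object@nVertices))
    return("edge endpoints out of range")
  if (any(object@edges[, 1L] >= object@edges[, 2L]))
    return("edges must be stored once with i < j")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  deg <- tabulate(object@edges, nbins = object@nVertices)
  if (any(deg == 0L)) return("every vertex needs at least one edge")
  TRUE
})

#' ProbabilityField: per-pixel, per-label random-walker probabilities
#'
#' Row `p` gives the probability that a random walker released at pixel `p`
#' first reaches a seed of each label.  Seed rows are one-hot; rows sum to 1.
#'
#' @slot probs numeric matrix `(nP, nM)` with entries in `[0, 1]`.
#' @slot dim integer spatial shape `(rows, cols)`.
#' @seealso [solveDirichlet()]
#' @export
setClass("ProbabilityField", slots = c(probs = "matrix", dim = "integer"))

setValidity("ProbabilityField", function(object) {
  x <- object@probs
  if (nrow(x) != prod(object@dim))
    return("one row per pixel is required")
  if (any(x < -1e-10) || any(x > 1 + 1e-10))
    return("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(x) - 1) > 1e-8))
    return("rows must sum to 1")
  TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube: %d bands, %d x %d pixels\n", d[1L], d[2L], d[3L]))
  if (length(object@wavelength))
    cat(sprintf("  wavelengths: %.1f - %.1f nm\n",
                min(object@wavelength), max(object@wavelength)))
})

setMethod("show", "LabelMask", function(object) {
  tab <- table(object@labels[object@labels > 0])
  cat(sprintf("LabelMask: %d x %d pixels, %d regions (%d marked pixels)\n",
              nrow(object@labels), ncol(object@labels), length(tab),
              sum(tab)))
})

setMethod("show", "SegmentationMap", function(object) {
  cat(sprintf("SegmentationMap: %d x %d pixels, %d labels\n",
              nrow(object@labels), ncol(object@labels),
              length(unique(as.vector(object@labels)))))
})

setMethod("show", "FeatureImage", function(object) {
  cat(sprintf("FeatureImage: %d features, %d x %d pixels\n",
              nrow(object@values), object@dim[1L], object@dim[2L]))
})

setMethod("show", "PatchFeatureSet", function(object) {
  cat(sprintf(
    "PatchFeatureSet: %d x %d pixels, window %d (Nb = %d), l = %d\n",
    object@dim[1L], object@dim[2L], object@window,
    nrow(object@values) / object@nFeatures, object@nFeatures))
})

setMethod("show", "PixelGraph", function(object) {
  cat(sprintf("PixelGraph: %d vertices, %d edges, %d-connectivity\n",
              object@nVertices, nrow(object@edges), object@connectivity))
})

setMethod("show", "ProbabilityField", function(object) {
  cat(sprintf("ProbabilityField: %d pixels x %d labels\n",
              nrow(object@probs), ncol(object@probs)))
})

## ---- accessors ------------------------------------------------------------

#' @describeIn HyperCube-class number of spectral bands m.
#' @param x a package object.
#' @export
nBands <- function(x) dim(x@data)[1L]

#' Spatial shape of an image-like object
#'
#' @param x a [HyperCube-class], [LabelMask-class], [SegmentationMap-class],
#'   [FeatureImage-class] or [PatchFeatureSet-class].
#' @return integer `(rows, cols)`.
#' @export
spatialShape <- function(x) {
  if (is(x, "HyperCube")) return(dim(x@data)[2:3])
  if (is(x, "LabelMask") || is(x, "SegmentationMap")) return(dim(x@labels))
  x@dim
}

#' Number of pixels
#' @param x an image-like object (see [spatialShape()]).
#' @export
nPixels <- function(x) prod(spatialShape(x))

#' Number of marked regions nM in a mask
#' @param x a [LabelMask-class].
#' @export
nRegions <- function(x) max(x@labels)

#' Flatten a cube to the (bands x pixels) data matrix
#'
#' Returns `X0` with one column per pixel in row-major pixel order
#' (column index `p = (r - 1) * C + c`).
#'
#' @param x a [HyperCube-class].
#' @return numeric matrix `(m, nP)`.
#' @export
pixelMatrix <- function(x) {
  d <- x@data
  matrix(aperm(d, c(1L, 3L, 2L)), nrow = dim(d)[1L])
}

#' Label raster of a mask or segmentation
#' @param x a [LabelMask-class] or [SegmentationMap-class].
#' @return integer matrix `(rows, cols)`.
#' @export
labelMatrix <- function(x) x@labels

#' Labels flattened in row-major pixel order
#' @param x a [LabelMask-class] or [SegmentationMap-class].
#' @export
labelVector <- function(x) as.vector(t(x@labels))

#' Feature matrix of a feature image or patch feature set
#' @param x a [FeatureImage-class] or [PatchFeatureSet-class].
#' @return numeric matrix with one column per pixel.
#' @export
featureMatrix <- function(x) x@values

#' Probability matrix of a probability field
#' @param x a [ProbabilityField-class].
#' @return numeric matrix `(nP, nM)`.
#' @export
probabilityMatrix <- function(x) x@probs
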