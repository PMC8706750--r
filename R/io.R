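#' Read a hyperspectral cube from disk
#'
#' Supported formats: ENVI raster (flat binary plus `.hdr` text header; BSQ,
#' BIL and BIP interleaves), an R `.rds` serialization of a 3-D array, and a
#' long-format CSV with columns `band,row,col,value`.  Whatever the on-disk
#' layout, the cube is returned in canonical `(band, row, col)` order.
#' The `rds` and `csv` forms stand in for MAT-file / NPZ archives common in
#' the hyperspectral community, for which no reader is available here.
#'
#' For `rds` files holding a list (e.g. a converted MAT-file workspace), the
#' unique 3-D numeric element is taken; it is an error if none or several
#' qualify.
#'
#' @param path path to the data file (for ENVI, the binary; the header is
#'   `<path>.hdr` or the `.hdr`-swapped extension).
#' @param format one of `"auto"`, `"envi"`, `"rds"`, `"csv"`; `"auto"` keys
#'   on the file extension.
#' @return A [HyperCube-class].
#' @examples
#' cube <- HyperCube(array(runif(24), c(4, 2, 3)))
#' f <- tempfile(fileext = ".rds")
#' saveCube(cube, f)
#' identical(loadCube(f)@data, cube@data)
#' @export
loadCube <- function(path, format = c("auto", "envi", "rds", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("cannot read cube: no such file '%s'", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, rds = "rds", csv = "csv", "envi")
  }
  arr <- switch(format,
    rds  = .cubeFromR(readRDS(path)),
    csv  = .readCubeCSV(path),
    envi = .readENVI(path))
  if (length(dim(arr)) != 3L)
    .stopf("cube data must be 3-dimensional, got %d dimension(s)",
           length(dim(arr)))
  storage.mode(arr) <- "double"
  HyperCube(arr)
}

# accept a bare 3-D array or a list with a unique 3-D numeric element
.cubeFromR <- function(obj) {
  if (is.array(obj)) return(obj)
  if (is.list(obj)) {
    is3d <- vapply(obj, function(x)
      is.numeric(x) && length(dim(x)) == 3L, logical(1))
    if (sum(is3d) == 1L) return(obj[[which(is3d)]])
    if (sum(is3d) == 0L) .stopf("no 3-D numeric array found in file")
    .stopf("ambiguous file: %d candidate 3-D arrays (%s)",
           sum(is3d), paste(names(obj)[is3d], collapse = ", "))
  }
  obj
}

.readCubeCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("band", "row", "col", "value")
  if (!all(need %in% names(df)))
    .stopf("cube CSV needs columns %s", paste(need, collapse = ", "))
  m <- max(df$band); R <- max(df$row); C <- max(df$col)
  arr <- array(NA_real_, c(m, R, C))
  arr[cbind(df$band, df$row, df$col)] <- df$value
  if (anyNA(arr)) .stopf("cube CSV does not cover the full (band,row,col) grid")
  arr
}

#' Write a hyperspectral cube
#'
#' @param cube a [HyperCube-class].
#' @param path output path; format from extension unless given.
#' @param format `"auto"`, `"envi"`, `"rds"` or `"csv"`.
#' @param interleave ENVI interleave to write: `"bsq"`, `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @export
saveCube <- function(cube, path, format = c("auto", "envi", "rds", "csv"),
                     interleave = c("bsq", "bil", "bip")) {
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  if (!dir.exists(dirname(path)))
    .stopf("cannot write '%s': directory does not exist", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, rds = "rds", csv = "csv", "envi")
  }
  switch(format,
    rds = saveRDS(cube@data, path),
    csv = {
      d <- dim(cube@data)
      idx <- expand.grid(band = seq_len(d[1L]), row = seq_len(d[2L]),
                         col = seq_len(d[3L]))
      idx$value <- cube@data[as.matrix(idx)]
      utils::write.csv(idx, path, row.names = FALSE)
    },
    envi = .writeENVI(cube@data, path, interleave))
  invisible(path)
}

## ---- ENVI raster ----------------------------------------------------------
# minimal ENVI support: text header "key = value" plus flat binary body.
# data types 4 (float32) and 5 (float64); interleaves bsq/bil/bip.

.enviHeaderPath <- function(path) {
  cand <- c(paste0(path, ".hdr"),
            paste0(tools::file_path_sans_ext(path), ".hdr"))
  hit <- cand[file.exists(cand)]
  if (!length(hit)) .stopf("ENVI header not found for '%s'", path)
  hit[1L]
}

.readENVI <- function(path) {
  hdr <- readLines(.enviHeaderPath(path), warn = FALSE)
  getval <- function(key) {
    ln <- grep(sprintf("^\\s*%s\\s*=", key), hdr, value = TRUE,
               ignore.case = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub("^[^=]*=", "", ln[1L]))
  }
  C <- as.integer(getval("samples"))
  R <- as.integer(getval("lines"))
  m <- as.integer(getval("bands"))
  dtype <- as.integer(getval("data type"))
  il <- tolower(getval("interleave"))
  border <- getval("byte order")
  if (anyNA(c(C, R, m, dtype)))
    .stopf("ENVI header is missing samples/lines/bands/data type")
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 .stopf("unsupported ENVI data type %d", dtype))
  endian <- if (!is.na(border) && border == "1") "big" else "little"
  v <- readBin(path, what = "double", n = m * R * C, size = size,
               endian = endian)
  if (length(v) != m * R * C)
    .stopf("ENVI binary is truncated: expected %d values, got %d",
           m * R * C, length(v))
  # reorder the flat vector (fastest index first, per interleave) to (m,R,C)
  switch(il,
    bsq = aperm(array(v, c(C, R, m)), c(3L, 2L, 1L)),
    bil = aperm(array(v, c(C, m, R)), c(2L, 3L, 1L)),
    bip = aperm(array(v, c(m, C, R)), c(1L, 3L, 2L)),
    .stopf("unsupported ENVI interleave '%s'", il))
}

.writeENVI <- function(arr, path, interleave = "bsq") {
  d <- dim(arr); m <- d[1L]; R <- d[2L]; C <- d[3L]
  v <- switch(interleave,
    bsq = as.vector(aperm(arr, c(3L, 2L, 1L))),
    bil = as.vector(aperm(arr, c(3L, 1L, 2L))),
    bip = as.vector(aperm(arr, c(1L, 3L, 2L))))
  writeBin(v, path, size = 8L, endian = "little")
  hdr <- c("ENVI",
           sprintf("samples = %d", C),
           sprintf("lines = %d", R),
           sprintf("bands = %d", m),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           sprintf("interleave = %s", interleave),
           "byte order = 0")
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

## ---- masks and segmentations ----------------------------------------------

#' Read a seed / label mask
#'
#' Reads an integer raster (CSV matrix without header, or `.rds` of an
#' integer matrix), validates it, and infers the number of marked regions
#' `nM` as the maximum label.  A valid seed mask needs `nM >= 2` and every
#' label in `1..nM` nonempty; 0 marks unlabeled pixels.
#'
#' @param path path to the raster.
#' @return A [LabelMask-class].
#' @export
loadMask <- function(path) {
  if (!file.exists(path)) .stopf("cannot read mask: no such file '%s'", path)
  m <- if (tolower(tools::file_ext(path)) == "rds") readRDS(path)
       else as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  if (any(m < 0)) .stopf("mask contains negative labels")
  if (max(m) < 2) .stopf("a seed mask needs at least 2 marked regions")
  LabelMask(m)   # validity checks contiguity of 1..nM
}

#' Write a label mask as a headerless CSV raster
#' @param mask a [LabelMask-class].
#' @param path output path.
#' @export
saveMask <- function(mask, path) {
  if (!dir.exists(dirname(path)))
    .stopf("cannot write '%s': directory does not exist", path)
  utils::write.table(mask@labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a segmentation (and optional probability planes)
#'
#' The label raster goes to `path` as a headerless CSV of integers.  If a
#' [ProbabilityField-class] is supplied, one CSV plane per label is written
#' alongside as `<path-sans-ext>_prob<k>.csv` with 17 significant digits, so
#' that a reload reproduces the doubles exactly.
#'
#' @param seg a [SegmentationMap-class].
#' @param prob optional [ProbabilityField-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
saveSegmentation <- function(seg, prob = NULL, path) {
  if (!dir.exists(dirname(path)))
    .stopf("cannot write '%s': directory does not exist", path)
  utils::write.table(seg@labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(prob)) {
    base <- tools::file_path_sans_ext(path)
    for (k in seq_len(ncol(prob@probs))) {
      plane <- .unflattenRowMajor(prob@probs[, k], prob@dim)
      txt <- apply(plane, 1L, function(row)
        paste(formatC(row, digits = 17, format = "g"), collapse = ","))
      writeLines(txt, sprintf("%s_prob%d.csv", base, k))
    }
  }
  invisible(path)
}

#' Read back a segmentation written by [saveSegmentation()]
#' @param path CSV path.
#' @return A [SegmentationMap-class].
#' @export
loadSegmentation <- function(path) {
  if (!file.exists(path)) .stopf("no such file '%s'", path)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  SegmentationMap(m)
}

#' Read back probability planes written by [saveSegmentation()]
#' @param path the segmentation CSV path the planes accompany.
#' @param nLabels number of planes to read.
#' @return A [ProbabilityField-class].
#' @export
loadProbabilityField <- function(path, nLabels) {
  base <- tools::file_path_sans_ext(path)
  planes <- lapply(seq_len(nLabels), function(k) {
    f <- sprintf("%s_prob%d.csv", base, k)
    if (!file.exists(f)) .stopf("missing probability plane '%s'", f)
    as.matrix(utils::read.csv(f, header = FALSE))
  })
  dims <- dim(planes[[1L]])
  X <- vapply(planes, .flattenRowMajor, numeric(prod(dims)))
  new("ProbabilityField", probs = X, dim = as.integer(dims))
}
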