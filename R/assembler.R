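# Materialisation of one 5D hypercube per microscope position.

# Decode a raster plane to an integer matrix with attributes `bits`.
# PNG planes are treated as 8-bit (the png writer used throughout emits
# 8-bit samples).
.readPlane <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(m, "bits.per.sample")
    m <- unclass(m)
    attributes(m) <- list(dim = dim(m))
    storage.mode(m) <- "integer"
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # grayscale written, be safe
    m <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    bits <- 8L
  } else {
    stop("unsupported plane format: ", path)
  }
  attr(m, "bits") <- as.integer(bits)
  m
}

#' Assemble a five-dimensional hypercube from a plane index
#'
#' Reads every plane in the index exactly once and places it at its
#' (t, c, z) rank coordinates in a (T, C, Z, Y, X) array. All planes must
#' share height, width and pixel type; mixed shapes or bit depths are an
#' error naming both offending files (no implicit promotion). Grid cells
#' with no plane are an error under the default `"error"` fill policy;
#' `"zero"` substitutes all-zero planes (opt-in, since silently
#' fabricated planes corrupt quantitative data).
#'
#' @param index a [PlaneIndex-class] with at least one plane.
#' @param fillPolicy `"error"` (default) or `"zero"`.
#' @return A [HyperCube-class]; channel names are the channel tokens in
#'   rank order, provenance records each source plane.
#' @export
assembleCube <- function(index, fillPolicy = c("error", "zero")) {
  stopifnot(is(index, "PlaneIndex"))
  fillPolicy <- match.arg(fillPolicy)
  p <- index@planes
  if (!nrow(p)) stop("empty plane index for position ", index@positionId)
  ext <- index@extents
  nCells <- prod(ext)
  if (nrow(p) < nCells) {
    if (fillPolicy == "error") {
      have <- paste(p$tRank, p$cRank, p$zRank)
      grid <- expand.grid(z = seq_len(ext[3L]) - 1L,
                          c = seq_len(ext[2L]) - 1L,
                          t = seq_len(ext[1L]) - 1L)
      miss <- grid[!paste(grid$t, grid$c, grid$z) %in% have, ]
      stop("position ", index@positionId, ": ", nrow(miss),
           " missing grid cell(s) under fill policy 'error': ",
           paste(sprintf("(t=%d,c=%d,z=%d)", miss$t, miss$c, miss$z),
                 collapse = ", "))
    }
  }
  first <- .readPlane(p$path[1L])
  h <- nrow(first); w <- ncol(first); bits <- attr(first, "bits")
  arr <- array(0L, dim = c(ext, h, w))
  for (i in seq_len(nrow(p))) {
    m <- if (i == 1L) first else .readPlane(p$path[i])
    if (nrow(m) != h || ncol(m) != w)
      stop("inconsistent plane shapes: ", p$path[1L], " is ", h, "x", w,
           " but ", p$path[i], " is ", nrow(m), "x", ncol(m))
    if (!identical(attr(m, "bits"), bits))
      stop("inconsistent pixel types: ", p$path[1L], " is ", bits,
           "-bit but ", p$path[i], " is ", attr(m, "bits"), "-bit")
    arr[p$tRank[i] + 1L, p$cRank[i] + 1L, p$zRank[i] + 1L, , ] <- m
  }
  new("HyperCube", positionId = index@positionId, pixels = arr,
      channelNames = names(index@cRanks),
      pixelType = if (bits == 16L) "uint16" else "uint8",
      provenance = p[, c("tRank", "cRank", "zRank", "path")])
}

#' DefaultImageProcessor: the stock hypercube image processor
#'
#' The default implementation of the image-processor contract
#' ([processImage()]): scan `pos{xxx}` directories, build and validate a
#' plane index per position, assemble one hypercube each and write it
#' through the broker. Replaceable at runtime by any object with a
#' [processImage()] method (for example one that segments or denoises
#' before writing).
#'
#' @slot fillPolicy `"error"` or `"zero"`, passed to [assembleCube()].
#' @export DefaultImageProcessor
#' @exportClass DefaultImageProcessor
DefaultImageProcessor <- setClass(
  "DefaultImageProcessor",
  representation(fillPolicy = "character"),
  prototype(fillPolicy = "error"))

#' @describeIn processImage scan, validate, assemble and write one
#'   hypercube per position; duplicate plane coordinates are always an
#'   error, missing cells follow the processor's fill policy. Returns
#'   image references in ascending position order; an empty tree yields
#'   zero references and a warning in attribute `"warnings"`.
setMethod("processImage", "DefaultImageProcessor",
          function(processor, broker, path, dataset, ...) {
  pos <- scanPositions(path)
  warnings <- character()
  refs <- data.frame(positionId = integer(), file = character(),
                     stringsAsFactors = FALSE)
  if (!nrow(pos))
    warnings <- c(warnings, paste0("no pos{xxx} directories under ", path))
  for (i in seq_len(nrow(pos))) {
    bi <- buildIndex(pos$positionId[i], pos$dir[i])
    rep <- bi$report
    if (nrow(rep@rejected))
      warnings <- c(warnings, sprintf(
        "position %d: %d non-conforming file(s) ignored",
        pos$positionId[i], nrow(rep@rejected)))
    if (nrow(rep@duplicates))
      stop("position ", pos$positionId[i], ": duplicate plane coordinates: ",
           paste(rep@duplicates$path1, "/", rep@duplicates$path2,
                 collapse = "; "))
    cube <- assembleCube(bi$index,
                         fillPolicy = processor@fillPolicy)
    ref <- writeHypercube(broker, dataset, cube)
    refs <- rbind(refs, data.frame(positionId = ref$positionId,
                                   file = ref$file,
                                   stringsAsFactors = FALSE))
  }
  attr(refs, "warnings") <- warnings
  refs
})
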