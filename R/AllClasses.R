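#' @import methods
NULL

.PIXEL_TYPES <- c("uint8", "uint16")
.IMAGE_FORMATS <- c("tiff", "png")

#' Pixel-type maximum representable value
#' @param pixelType `"uint8"` or `"uint16"`.
#' @return Integer scalar: 255 or 65535.
#' @keywords internal
pixelTypeMax <- function(pixelType) {
  switch(match.arg(pixelType, .PIXEL_TYPES), uint8 = 255L, uint16 = 65535L)
}

#' LayoutSpec: the shape of a synthetic multi-position plane tree
#'
#' Describes a directory tree of 2D planes laid out the way multi-position
#' time-lapse acquisitions are stored on disk: one `pos{xxx}` subdirectory
#' per microscope stage position, each holding one raster file per
#' (timepoint, channel, z-section) combination, named
#' `{prefix}_{timepoint}_{channel}_{z}.{ext}`.
#'
#' @slot nPositions number of stage positions (subdirectories).
#' @slot timepoints ordered integer timepoint tokens (duplicate-free).
#' @slot channels ordered character channel tokens (duplicate-free).
#' @slot zSections ordered integer z-section tokens (duplicate-free).
#' @slot planeHeight,planeWidth plane dimensions in pixels.
#' @slot prefix the arbitrary leading part of every filename.
#' @slot imageFormat `"tiff"` or `"png"`.
#' @slot pixelType `"uint8"` or `"uint16"` (`"uint16"` requires TIFF:
#'   the PNG writer used here emits 8-bit samples only).
#' @exportClass LayoutSpec
setClass("LayoutSpec", representation(
  nPositions = "integer",
  timepoints = "integer",
  channels = "character",
  zSections = "integer",
  planeHeight = "integer",
  planeWidth = "integer",
  prefix = "character",
  imageFormat = "character",
  pixelType = "character"
))

setValidity("LayoutSpec", function(object) {
  msg <- character()
  if (length(object@nPositions) != 1L || is.na(object@nPositions) ||
      object@nPositions < 1L)
    msg <- c(msg, "nPositions must be a single positive integer")
  for (tok in c("timepoints", "channels", "zSections")) {
    v <- slot(object, tok)
    if (length(v) == 0L) msg <- c(msg, paste0(tok, " must be non-empty"))
    if (anyDuplicated(v)) msg <- c(msg, paste0(tok, " must be duplicate-free"))
    if (anyNA(v)) msg <- c(msg, paste0(tok, " must not contain NA"))
  }
  if (any(object@timepoints < 0L)) msg <- c(msg, "timepoints must be >= 0")
  if (any(object@zSections < 0L)) msg <- c(msg, "zSections must be >= 0")
  if (any(!nzchar(object@channels)))
    msg <- c(msg, "channel tokens must be non-empty strings")
  if (any(grepl("_", object@channels)))
    msg <- c(msg, "channel tokens must not contain underscores")
  if (object@planeHeight < 1L || object@planeWidth < 1L)
    msg <- c(msg, "plane dimensions must be >= 1")
  if (!object@imageFormat %in% .IMAGE_FORMATS)
    msg <- c(msg, "imageFormat must be 'tiff' or 'png'")
  if (!object@pixelType %in% .PIXEL_TYPES)
    msg <- c(msg, "pixelType must be 'uint8' or 'uint16'")
  if (identical(object@imageFormat, "png") &&
      identical(object@pixelType, "uint16"))
    msg <- c(msg, "uint16 planes require imageFormat 'tiff'")
  if (length(msg)) msg else TRUE
})

#' Construct a LayoutSpec
#'
#' @param nPositions number of `pos{xxx}` subdirectories.
#' @param timepoints integer timepoint tokens appearing in filenames.
#' @param channels channel tokens (coerced to character; kept verbatim).
#' @param zSections integer z-section tokens.
#' @param planeHeight,planeWidth plane size in pixels.
#' @param prefix leading filename string (may contain underscores).
#' @param imageFormat `"tiff"` (default) or `"png"`.
#' @param pixelType `"uint8"` (default) or `"uint16"`.
#' @return A validated [LayoutSpec-class] object.
#' @examples
#' LayoutSpec(3, timepoints = 1:3, channels = 1:3, zSections = 1)
#' @export
LayoutSpec <- function(nPositions, timepoints, channels, zSections,
                       planeHeight = 16L, planeWidth = 16L,
                       prefix = "img", imageFormat = c("tiff", "png"),
                       pixelType = c("uint8", "uint16")) {
  new("LayoutSpec",
      nPositions = as.integer(nPositions),
      timepoints = as.integer(timepoints),
      channels = as.character(channels),
      zSections = as.integer(zSections),
      planeHeight = as.integer(planeHeight),
      planeWidth = as.integer(planeWidth),
      prefix = as.character(prefix),
      imageFormat = match.arg(imageFormat),
      pixelType = match.arg(pixelType))
}

setMethod("show", "LayoutSpec", function(object) {
  cat(sprintf(
    "LayoutSpec: %d position(s) x %d timepoint(s) x %d channel(s) x %d z (%dx%d %s %s)\n",
    object@nPositions, length(object@timepoints), length(object@channels),
    length(object@zSections), object@planeHeight, object@planeWidth,
    object@pixelType, object@imageFormat))
})

#' MetadataBundle: the metadata-parser contract record
#'
#' Every metadata parser, default or user-supplied, returns exactly this
#' four-field record: a free-text description, a list of tag strings, an
#' ordered list of key-value pairs and a list of named tables. Empty
#' fields are permitted; missing fields are not.
#'
#' @slot description single string (possibly empty).
#' @slot tags character vector of tag labels.
#' @slot kvps two-column character `data.frame` (`key`, `value`) in file
#'   order.
#' @slot tables named list of `data.frame`s of character columns; the list
#'   names are the table names.
#' @exportClass MetadataBundle
setClass("MetadataBundle", representation(
  description = "character",
  tags = "character",
  kvps = "data.frame",
  tables = "list"
))

setValidity("MetadataBundle", function(object) {
  msg <- character()
  if (length(object@description) != 1L)
    msg <- c(msg, "description must be a single string")
  if (!identical(names(object@kvps), c("key", "value")))
    msg <- c(msg, "kvps must have columns 'key' and 'value'")
  if (length(object@tables)) {
    nm <- names(object@tables)
    if (is.null(nm) || any(!nzchar(nm)))
      msg <- c(msg, "every table must have a non-empty name")
    bad <- !vapply(object@tables, is.data.frame, logical(1))
    if (any(bad)) msg <- c(msg, "tables must be data.frames")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetadataBundle
#'
#' @param description free-text dataset description.
#' @param tags character vector of tags.
#' @param kvps a two-column `data.frame` (`key`, `value`), a named
#'   character vector, or a list of length-2 character vectors.
#' @param tables named list of `data.frame`s (all cells coerced to
#'   character).
#' @return A validated [MetadataBundle-class].
#' @examples
#' MetadataBundle(description = "test run",
#'                tags = c("timelapse", "yeast"),
#'                kvps = c(Microscope = "Nikon Ti"))
#' @export
MetadataBundle <- function(description = "", tags = character(),
                           kvps = NULL, tables = list()) {
  if (is.null(kvps)) {
    kvps <- data.frame(key = character(), value = character(),
                       stringsAsFactors = FALSE)
  } else if (is.data.frame(kvps)) {
    kvps <- data.frame(key = as.character(kvps$key),
                       value = as.character(kvps$value),
                       stringsAsFactors = FALSE)
  } else if (is.list(kvps)) {
    kvps <- data.frame(key = vapply(kvps, function(p) as.character(p[[1]]), ""),
                       value = vapply(kvps, function(p) as.character(p[[2]]), ""),
                       stringsAsFactors = FALSE)
  } else {  # named character vector
    kvps <- data.frame(key = names(kvps), value = unname(as.character(kvps)),
                       stringsAsFactors = FALSE)
  }
  tables <- lapply(tables, function(tb) {
    tb <- as.data.frame(tb, stringsAsFactors = FALSE)
    tb[] <- lapply(tb, as.character)
    rownames(tb) <- NULL
    tb
  })
  new("MetadataBundle", description = as.character(description),
      tags = as.character(tags), kvps = kvps, tables = tables)
}

setMethod("show", "MetadataBundle", function(object) {
  cat("MetadataBundle\n")
  d <- object@description
  cat(sprintf("  description: %s\n",
              if (nzchar(d)) substr(gsub("\n", " ", d), 1, 60) else "<empty>"))
  cat(sprintf("  tags: %s\n",
              if (length(object@tags)) paste(object@tags, collapse = ", ")
              else "<none>"))
  cat(sprintf("  kvps: %d  tables: %d\n", nrow(object@kvps),
              length(object@tables)))
})

#' FixtureManifest: ground truth for a generated tree
#'
#' @slot root tree root directory.
#' @slot planes `data.frame` with one row per generated plane file:
#'   `position`, `path`, `prefix`, `timepoint`, `channel`, `z`, `fill`
#'   (the constant pixel value written into the plane).
#' @slot acqPath,logPath paths of the generated metadata text files
#'   (`NA` when none were written).
#' @slot bundle the ground-truth [MetadataBundle-class] the default
#'   parsers must recover.
#' @exportClass FixtureManifest
setClass("FixtureManifest", representation(
  root = "character",
  planes = "data.frame",
  acqPath = "character",
  logPath = "character",
  bundle = "MetadataBundle"
))

setMethod("show", "FixtureManifest", function(object) {
  cat(sprintf("FixtureManifest: %d plane file(s) under %s\n",
              nrow(object@planes), object@root))
})

#' PlaneKey: the parsed identity of one 2D plane file
#'
#' @slot prefix arbitrary leading string (may contain underscores).
#' @slot timepoint integer timepoint token.
#' @slot channel channel token, kept verbatim as a string.
#' @slot z integer z-section token.
#' @slot path source file path (may be empty when parsed from a bare name).
#' @exportClass PlaneKey
setClass("PlaneKey", representation(
  prefix = "character",
  timepoint = "integer",
  channel = "character",
  z = "integer",
  path = "character"
))

setValidity("PlaneKey", function(object) {
  msg <- character()
  if (object@timepoint < 0L) msg <- c(msg, "timepoint must be >= 0")
  if (object@z < 0L) msg <- c(msg, "z must be >= 0")
  if (!nzchar(object@channel)) msg <- c(msg, "channel must be non-empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlaneKey", function(object) {
  cat(sprintf("PlaneKey: prefix='%s' t=%d c='%s' z=%d\n",
              object@prefix, object@timepoint, object@channel, object@z))
})

#' PlaneIndex: validated per-position plane map with dimension extents
#'
#' Rank maps translate the raw tokens found in filenames into dense
#' 0-based coordinates: distinct timepoint (and z) tokens are sorted
#' numerically; channel tokens numerically when all parse as integers,
#' lexicographically otherwise. Extents are the counts of distinct tokens.
#'
#' @slot positionId numeric id from the `pos{xxx}` directory name.
#' @slot dir the position directory.
#' @slot tRanks,cRanks,zRanks named integer vectors mapping token
#'   (as character) to 0-based rank.
#' @slot planes `data.frame`: `path`, `file`, `prefix`, `timepoint`,
#'   `channel`, `z`, `tRank`, `cRank`, `zRank` — one row per plane kept
#'   in the map (first file wins on duplicated coordinates).
#' @slot extents integer `c(SizeT, SizeC, SizeZ)`.
#' @exportClass PlaneIndex
setClass("PlaneIndex", representation(
  positionId = "integer",
  dir = "character",
  tRanks = "integer",
  cRanks = "integer",
  zRanks = "integer",
  planes = "data.frame",
  extents = "integer"
))

setValidity("PlaneIndex", function(object) {
  msg <- character()
  if (length(object@extents) != 3L)
    msg <- c(msg, "extents must be c(SizeT, SizeC, SizeZ)")
  else {
    if (length(object@tRanks) != object@extents[1L] ||
        length(object@cRanks) != object@extents[2L] ||
        length(object@zRanks) != object@extents[3L])
      msg <- c(msg, "extents must equal the number of distinct tokens")
    p <- object@planes
    if (nrow(p)) {
      if (any(p$tRank < 0L | p$tRank >= object@extents[1L]) ||
          any(p$cRank < 0L | p$cRank >= object@extents[2L]) ||
          any(p$zRank < 0L | p$zRank >= object@extents[3L]))
        msg <- c(msg, "plane ranks must lie within extents")
      if (anyDuplicated(p[, c("tRank", "cRank", "zRank")]))
        msg <- c(msg, "plane map must be injective over (t, c, z) ranks")
      if (anyDuplicated(p$path))
        msg <- c(msg, "plane map must be injective over file paths")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlaneIndex", function(object) {
  cat(sprintf("PlaneIndex: position %d, %d plane(s), extents T=%d C=%d Z=%d\n",
              object@positionId, nrow(object@planes),
              object@extents[1L], object@extents[2L], object@extents[3L]))
})

#' ValidationReport: completeness check for a PlaneIndex
#'
#' @slot missing `data.frame` (`tRank`, `cRank`, `zRank`) of grid cells
#'   with no plane file.
#' @slot duplicates `data.frame` (`path1`, `path2`) of file pairs mapping
#'   to the same (t, c, z) coordinate.
#' @slot rejected `data.frame` (`file`, `reason`) of non-conforming
#'   filenames.
#' @slot isComplete `TRUE` iff `missing` and `duplicates` are both empty.
#' @exportClass ValidationReport
setClass("ValidationReport", representation(
  missing = "data.frame",
  duplicates = "data.frame",
  rejected = "data.frame",
  isComplete = "logical"
))

setValidity("ValidationReport", function(object) {
  ok <- nrow(object@missing) == 0L && nrow(object@duplicates) == 0L
  if (!identical(object@isComplete, ok))
    "isComplete must equal (no missing cells and no duplicates)"
  else TRUE
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf(
    "ValidationReport: %s (%d missing, %d duplicate pair(s), %d rejected file(s))\n",
    if (object@isComplete) "complete" else "INCOMPLETE",
    nrow(object@missing), nrow(object@duplicates), nrow(object@rejected)))
})

#' HyperCube: one five-dimensional image for one microscope position
#'
#' Pixels are held in canonical (T, C, Z, Y, X) axis order; sinks convert
#' to their declared on-disk dimension order when writing.
#'
#' @slot positionId microscope position id.
#' @slot pixels 5-axis integer array, dim = c(SizeT, SizeC, SizeZ, SizeY,
#'   SizeX).
#' @slot channelNames channel names in rank order (duplicate-free,
#'   length SizeC).
#' @slot pixelType `"uint8"` or `"uint16"`, as read from the planes.
#' @slot provenance `data.frame` (`tRank`, `cRank`, `zRank`, `path`) of
#'   source planes; zero-filled cells are absent.
#' @exportClass HyperCube
setClass("HyperCube", representation(
  positionId = "integer",
  pixels = "array",
  channelNames = "character",
  pixelType = "character",
  provenance = "data.frame"
))

setValidity("HyperCube", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 5L)
    msg <- c(msg, "pixels must be a 5-axis (T, C, Z, Y, X) array")
  else if (length(object@channelNames) != d[2L])
    msg <- c(msg, "channelNames must have length SizeC")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be duplicate-free")
  if (!object@pixelType %in% .PIXEL_TYPES)
    msg <- c(msg, "pixelType must be 'uint8' or 'uint16'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "HyperCube: position %d, T=%d C=%d Z=%d Y=%d X=%d (%s), channels: %s\n",
    object@positionId, d[1L], d[2L], d[3L], d[4L], d[5L], object@pixelType,
    paste(object@channelNames, collapse = ", ")))
})

#' DatasetRef: a dataset handle within a sink
#'
#' @slot datasetId opaque identifier, unique within the sink.
#' @slot name the requested dataset name.
#' @slot location dataset directory (local sink) or server address.
#' @exportClass DatasetRef
setClass("DatasetRef", representation(
  datasetId = "character",
  name = "character",
  location = "character"
))

setMethod("show", "DatasetRef", function(object) {
  cat(sprintf("DatasetRef: '%s' (id %s) at %s\n",
              object@name, object@datasetId, object@location))
})

#' AnnotationManifest: sink-side record of what was deposited
#'
#' @slot datasetName dataset name.
#' @slot description dataset description.
#' @slot tags tag labels attached to the dataset.
#' @slot kvps two-column `data.frame` (`key`, `value`).
#' @slot tableFiles filenames of the `.h5` table attachments (one per
#'   table in the bundle).
#' @slot images `data.frame` with one row per written hypercube:
#'   `positionId`, `file`, `sizeT`, `sizeC`, `sizeZ`, `sizeY`, `sizeX`,
#'   `channels` (comma-joined names).
#' @exportClass AnnotationManifest
setClass("AnnotationManifest", representation(
  datasetName = "character",
  description = "character",
  tags = "character",
  kvps = "data.frame",
  tableFiles = "character",
  images = "data.frame"
))

setMethod("show", "AnnotationManifest", function(object) {
  cat(sprintf(
    "AnnotationManifest: dataset '%s', %d image(s), %d tag(s), %d kvp(s), %d table file(s)\n",
    object@datasetName, nrow(object@images), length(object@tags),
    nrow(object@kvps), length(object@tableFiles)))
})

#' UploadReport: outcome of one end-to-end deposition
#'
#' @slot datasetName name of the created dataset.
#' @slot datasetId its identifier within the sink.
#' @slot imagesWritten number of hypercube images deposited.
#' @slot planesWritten total 2D planes across all images
#'   (sum of SizeT x SizeC x SizeZ).
#' @slot tagsWritten,kvpsWritten,tablesWritten annotation counts.
#' @slot warnings character vector of non-fatal issues.
#' @exportClass UploadReport
setClass("UploadReport", representation(
  datasetName = "character",
  datasetId = "character",
  imagesWritten = "integer",
  planesWritten = "integer",
  tagsWritten = "integer",
  kvpsWritten = "integer",
  tablesWritten = "integer",
  warnings = "character"
))

setMethod("show", "UploadReport", function(object) {
  cat("Upload report\n")
  cat(sprintf("  dataset: %s (id %s)\n", object@datasetName,
              object@datasetId))
  cat(sprintf("  images deposited: %d\n", object@imagesWritten))
  cat(sprintf("  planes written:   %d\n", object@planesWritten))
  cat(sprintf("  annotations: %d tag(s), %d key-value pair(s), %d table(s)\n",
              object@tagsWritten, object@kvpsWritten, object@tablesWritten))
  if (length(object@warnings))
    cat("  warnings:\n", paste0("    - ", object@warnings, "\n"), sep = "")
})
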