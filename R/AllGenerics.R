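#' Extract metadata from a source (the pluggable parser contract)
#'
#' The single operation every metadata parser must provide. Implementations
#' registered against this generic are substitutable at runtime: the upload
#' orchestration only ever calls `extractMetadata(parser, source)` and
#' expects a [MetadataBundle-class] back.
#'
#' @param parser a parser object (see [MetadataParser-class]).
#' @param source a text-file path for leaf parsers, or a tree root
#'   directory for aggregating parsers.
#' @param ... passed to methods.
#' @return A [MetadataBundle-class].
#' @export
setGeneric("extractMetadata", function(parser, source, ...)
  standardGeneric("extractMetadata"))

#' Process a scanned image tree into deposited images
#'
#' The pluggable image-processor contract: given a broker handle, a tree
#' root and a target dataset, transform the raw 2D planes into images in
#' the sink and return their references. The default implementation
#' assembles one five-dimensional hypercube per `pos{xxx}` directory; any
#' object with a method for this generic may replace it.
#'
#' @param processor a processor object (see
#'   [DefaultImageProcessor-class]).
#' @param broker a data broker / sink handle.
#' @param path the scanned tree root.
#' @param dataset a [DatasetRef-class] in the sink.
#' @param ... passed to methods.
#' @return A `data.frame` of image references in ascending position order
#'   (columns `positionId`, `file`), with attribute `"warnings"`.
#' @export
setGeneric("processImage", function(processor, broker, path, dataset, ...)
  standardGeneric("processImage"))

#' Create a dataset in a sink
#' @param broker a broker / sink handle.
#' @param name dataset name (non-empty).
#' @param ... passed to methods.
#' @return A [DatasetRef-class].
#' @export
setGeneric("createDataset", function(broker, name, ...)
  standardGeneric("createDataset"))

#' Write a hypercube image into a dataset
#' @param broker a broker / sink handle.
#' @param dataset a [DatasetRef-class].
#' @param cube a [HyperCube-class].
#' @param ... passed to methods.
#' @return An image reference (named list with at least `positionId` and
#'   `file`).
#' @export
setGeneric("writeHypercube", function(broker, dataset, cube, ...)
  standardGeneric("writeHypercube"))

#' Link a metadata bundle to a dataset
#' @param broker a broker / sink handle.
#' @param dataset a [DatasetRef-class].
#' @param bundle a [MetadataBundle-class].
#' @param ... passed to methods.
#' @return An [AnnotationManifest-class].
#' @export
setGeneric("annotateDataset", function(broker, dataset, bundle, ...)
  standardGeneric("annotateDataset"))

#' @name accessors
#' @title Accessors for omeDeposit objects
#' @description Small accessor generics: `extents()` returns the
#'   (SizeT, SizeC, SizeZ) grid of an index or cube, `channelNames()` the
#'   channel names in rank order, `pixelArray()` the raw (T, C, Z, Y, X)
#'   array, `positionId()` the microscope position id, and
#'   `description()`/`metaTags()`/`kvps()`/`metaTables()` the four fields
#'   of a [MetadataBundle-class].
#' @param object an omeDeposit object.
#' @return See description.
NULL

#' @rdname accessors
#' @export
setGeneric("extents", function(object) standardGeneric("extents"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("pixelArray", function(object) standardGeneric("pixelArray"))

#' @rdname accessors
#' @export
setGeneric("positionId", function(object) standardGeneric("positionId"))

#' @rdname accessors
#' @export
setGeneric("description", function(object) standardGeneric("description"))

#' @rdname accessors
#' @export
setGeneric("metaTags", function(object) standardGeneric("metaTags"))

#' @rdname accessors
#' @export
setGeneric("kvps", function(object) standardGeneric("kvps"))

#' @rdname accessors
#' @export
setGeneric("metaTables", function(object) standardGeneric("metaTables"))

#' @rdname accessors
setMethod("extents", "PlaneIndex", function(object) {
  stats::setNames(object@extents, c("sizeT", "sizeC", "sizeZ"))
})

#' @rdname accessors
setMethod("extents", "HyperCube", function(object) {
  stats::setNames(dim(object@pixels),
                  c("sizeT", "sizeC", "sizeZ", "sizeY", "sizeX"))
})

#' @rdname accessors
setMethod("channelNames", "PlaneIndex", function(object) names(object@cRanks))

#' @rdname accessors
setMethod("channelNames", "HyperCube", function(object) object@channelNames)

#' @rdname accessors
setMethod("pixelArray", "HyperCube", function(object) object@pixels)

#' @rdname accessors
setMethod("positionId", "PlaneIndex", function(object) object@positionId)

#' @rdname accessors
setMethod("positionId", "HyperCube", function(object) object@positionId)

#' @rdname accessors
setMethod("description", "MetadataBundle", function(object) object@description)

#' @rdname accessors
setMethod("metaTags", "MetadataBundle", function(object) object@tags)

#' @rdname accessors
setMethod("kvps", "MetadataBundle", function(object) object@kvps)

#' @rdname accessors
setMethod("metaTables", "MetadataBundle", function(object) object@tables)
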