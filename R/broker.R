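# The deposition layer. The broker contract (createDataset /
# writeHypercube / annotateDataset) abstracts the destination; the local
# sink implements it fully on the filesystem — OME-TIFF images, HDF5
# table attachments and a JSON annotation manifest per dataset — so the
# entire pipeline runs and is testable without a server. A remote
# transport honouring the same generics can be slotted in unchanged.

#' Broker classes
#'
#' @description
#' `DataBroker` is the virtual base of the deposition layer; concrete
#' brokers provide methods for [createDataset()], [writeHypercube()] and
#' [annotateDataset()].
#'
#' `LocalSink` is the filesystem implementation: each dataset is a
#' directory containing one `pos{NNN}.ome.tiff` per hypercube, one `.h5`
#' file per attached table and a `manifest.json` recording the dataset
#' name, description, tags, key-value pairs, table attachments and image
#' dimensions.
#'
#' `RemoteBroker` declares the shape of a server-backed transport
#' (session credentials, host); no such transport is implemented here —
#' the class exists so one can be added without touching the
#' orchestration.
#'
#' @slot root (`LocalSink`) sink root directory; datasets are created
#'   beneath it.
#' @slot host,user (`RemoteBroker`) server coordinates.
#' @aliases DataBroker-class LocalSink-class RemoteBroker-class
#' @name DataBroker-class
#' @exportClass DataBroker
setClass("DataBroker", representation("VIRTUAL"))

#' @rdname DataBroker-class
#' @exportClass LocalSink
setClass("LocalSink", contains = "DataBroker",
         representation(root = "character"))

#' @rdname DataBroker-class
#' @exportClass RemoteBroker
setClass("RemoteBroker", contains = "DataBroker",
         representation("VIRTUAL", host = "character", user = "character"))

#' @rdname DataBroker-class
#' @param root sink root directory (created if absent).
#' @export
LocalSink <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root) || file.access(root, 2L) != 0L)
    stop("sink root not writable: ", root)
  new("LocalSink", root = normalizePath(root))
}

setMethod("show", "LocalSink", function(object) {
  cat("LocalSink at", object@root, "\n")
})

.emptyManifest <- function(name) {
  list(dataset = name, description = "", tags = character(),
       kvps = list(), tables = character(), images = list())
}

.manifestPath <- function(dataset) file.path(dataset@location,
                                             "manifest.json")

.readManifestList <- function(dataset) {
  jsonlite::read_json(.manifestPath(dataset), simplifyVector = FALSE)
}

.writeManifestList <- function(dataset, m) {
  jsonlite::write_json(m, .manifestPath(dataset), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' @describeIn createDataset create a dataset directory under the sink
#'   root (name sanitised of path separators; a repeated name gets a
#'   numeric suffix `_2`, `_3`, ...) holding an empty manifest.
setMethod("createDataset", "LocalSink", function(broker, name, ...) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    stop("dataset name must be non-empty")
  san <- gsub("[/\\\\]+", "_", trimws(name))
  id <- san
  k <- 2L
  while (dir.exists(file.path(broker@root, id))) {
    id <- sprintf("%s_%d", san, k)
    k <- k + 1L
  }
  loc <- file.path(broker@root, id)
  dir.create(loc)
  ds <- new("DatasetRef", datasetId = id, name = name, location = loc)
  .writeManifestList(ds, .emptyManifest(name))
  ds
})

#' @describeIn writeHypercube write `pos{NNN}.ome.tiff` into the dataset
#'   directory via [writeOmeTiff()] and append the image entry (position,
#'   file, sizes, channel names) to the manifest. Writing the same
#'   position twice into one dataset is a conflict error.
setMethod("writeHypercube", "LocalSink", function(broker, dataset, cube,
                                                  ...) {
  stopifnot(is(cube, "HyperCube"))
  fn <- sprintf("pos%03d.ome.tiff", cube@positionId)
  path <- file.path(dataset@location, fn)
  if (file.exists(path))
    stop("image for position ", cube@positionId,
         " already exists in dataset '", dataset@datasetId, "'")
  writeOmeTiff(cube, path)
  d <- dim(cube@pixels)
  entry <- list(positionId = cube@positionId, file = fn,
                sizeT = d[1L], sizeC = d[2L], sizeZ = d[3L],
                sizeY = d[4L], sizeX = d[5L],
                channels = as.list(cube@channelNames))
  m <- .readManifestList(dataset)
  m$images[[length(m$images) + 1L]] <- entry
  .writeManifestList(dataset, m)
  list(positionId = cube@positionId, file = fn)
})

.sanitizeFileStem <- function(x) {
  s <- gsub("[^A-Za-z0-9._-]+", "_", x)
  ifelse(nzchar(s), s, "table")
}

# One HDF5 file per table: a single group named after the table, one
# string dataset per column, and a "columns" group attribute preserving
# column order.
.writeTableH5 <- function(path, name, df) {
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("could not create HDF5 file for table '", name, "'")
  tryCatch({
    rhdf5::h5createGroup(path, name)
    for (cl in names(df))
      rhdf5::h5write(as.character(df[[cl]]), path, paste0(name, "/", cl))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, name)
    rhdf5::h5writeAttribute(names(df), gid, "columns")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }, error = function(e) {
    stop("serialization of table '", name, "' failed: ",
         conditionMessage(e))
  })
  invisible(path)
}

#' Read a table attachment back from HDF5
#'
#' @param path an `.h5` file written by [annotateDataset()].
#' @return A named list of one character `data.frame` per group, columns
#'   in stored order.
#' @export
readTableH5 <- function(path) {
  ls <- rhdf5::h5ls(path)
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  out <- list()
  for (g in groups) {
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    cols <- rhdf5::h5readAttributes(fid, g)$columns
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
    df <- as.data.frame(
      lapply(stats::setNames(cols, cols),
             function(cl) as.character(rhdf5::h5read(path,
                                                     paste0(g, "/", cl)))),
      stringsAsFactors = FALSE, check.names = FALSE)
    out[[g]] <- df
  }
  out
}

.manifestToS4 <- function(m) {
  kv <- if (length(m$kvps))
    data.frame(key = vapply(m$kvps, function(p) p[[1L]], ""),
               value = vapply(m$kvps, function(p) p[[2L]], ""),
               stringsAsFactors = FALSE)
  else data.frame(key = character(), value = character(),
                  stringsAsFactors = FALSE)
  imgs <- if (length(m$images))
    do.call(rbind, lapply(m$images, function(e)
      data.frame(positionId = as.integer(e$positionId), file = e$file,
                 sizeT = as.integer(e$sizeT), sizeC = as.integer(e$sizeC),
                 sizeZ = as.integer(e$sizeZ), sizeY = as.integer(e$sizeY),
                 sizeX = as.integer(e$sizeX),
                 channels = paste(unlist(e$channels), collapse = ","),
                 stringsAsFactors = FALSE)))
  else data.frame(positionId = integer(), file = character(),
                  sizeT = integer(), sizeC = integer(), sizeZ = integer(),
                  sizeY = integer(), sizeX = integer(),
                  channels = character(), stringsAsFactors = FALSE)
  new("AnnotationManifest", datasetName = m$dataset,
      description = if (is.null(m$description)) "" else m$description,
      tags = as.character(unlist(m$tags)), kvps = kv,
      tableFiles = as.character(unlist(m$tables)), images = imgs)
}

#' @describeIn annotateDataset record description, tags and key-value
#'   pairs in the manifest and serialise each named table to its own
#'   HDF5 attachment (one group per table, one named string array per
#'   column) in the dataset directory.
setMethod("annotateDataset", "LocalSink", function(broker, dataset, bundle,
                                                   ...) {
  stopifnot(is(bundle, "MetadataBundle"))
  validObject(bundle)
  m <- .readManifestList(dataset)
  m$description <- bundle@description
  m$tags <- as.list(bundle@tags)
  m$kvps <- lapply(seq_len(nrow(bundle@kvps)), function(i)
    list(bundle@kvps$key[i], bundle@kvps$value[i]))
  files <- character()
  for (nm in names(bundle@tables)) {
    stem <- .sanitizeFileStem(nm)
    fn <- paste0(stem, ".h5")
    k <- 2L
    while (fn %in% files) {
      fn <- sprintf("%s_%d.h5", stem, k)
      k <- k + 1L
    }
    fp <- file.path(dataset@location, fn)
    if (file.exists(fp)) unlink(fp)
    .writeTableH5(fp, nm, bundle@tables[[nm]])
    files <- c(files, fn)
  }
  m$tables <- as.list(files)
  .writeManifestList(dataset, m)
  .manifestToS4(m)
})

#' Read a dataset's annotation manifest
#'
#' @param dataset a [DatasetRef-class], or the path of a dataset
#'   directory containing `manifest.json`.
#' @return An [AnnotationManifest-class].
#' @export
readManifest <- function(dataset) {
  if (is.character(dataset))
    dataset <- new("DatasetRef", datasetId = basename(dataset),
                   name = basename(dataset), location = dataset)
  .manifestToS4(.readManifestList(dataset))
}

#' Run one end-to-end deposition
#'
#' The orchestration entry point: optionally parse metadata at the tree
#' root, create the dataset, process the image tree into hypercubes
#' through the broker, link the annotations and report. With a local
#' sink, `host` selects the sink directory (either a plain directory path
#' or the explicit form `local:<dir>`) and the credentials are ignored;
#' a remote transport would open a session with them, but none is
#' implemented here and any other `host` is an error.
#'
#' @param user,credential session credentials (unused by the local sink).
#' @param host sink selector: `local:<dir>`, or an existing/creatable
#'   directory path.
#' @param datasetName name of the dataset to create (non-empty).
#' @param dataPath tree root containing `pos{xxx}` directories and,
#'   optionally, `*Acq.txt` / `*log.txt` metadata files.
#' @param includeMetadata parse and attach metadata? When `FALSE` the
#'   dataset carries no tags, key-value pairs or tables.
#' @param parser a parser honouring [extractMetadata()]; default
#'   [MetadataAggregator()].
#' @param processor a processor honouring [processImage()]; default
#'   [DefaultImageProcessor-class].
#' @param sink an explicit [DataBroker-class], overriding `host`.
#' @return An [UploadReport-class]. A tree with no position directories
#'   yields zero images and a warning, not an error.
#' @examples
#' tree <- generateTree(LayoutSpec(2, 1:2, "GFP", 1), tempfile())
#' rpt <- launchUpload("u", "", tempfile(), "demo", tree@root,
#'                     includeMetadata = FALSE)
#' rpt@imagesWritten  # 2
#' @export
launchUpload <- function(user, credential, host, datasetName, dataPath,
                         includeMetadata = TRUE, parser = NULL,
                         processor = NULL, sink = NULL) {
  if (!dir.exists(dataPath)) stop("data path not found: ", dataPath)
  if (is.null(sink)) {
    if (startsWith(host, "local:")) {
      sink <- LocalSink(substring(host, 7L))
    } else if (grepl("^[A-Za-z0-9.-]+\\.[A-Za-z]{2,}(:[0-9]+)?$", host) &&
               !dir.exists(host)) {
      stop("remote transport to '", host, "' is not implemented; ",
           "use a local sink (host = 'local:<dir>' or a directory path)")
    } else {
      sink <- LocalSink(host)
    }
  }
  if (is.null(parser)) parser <- MetadataAggregator()
  if (is.null(processor)) processor <- DefaultImageProcessor()

  bundle <- if (includeMetadata) extractMetadata(parser, dataPath)
            else MetadataBundle()
  if (!is(bundle, "MetadataBundle"))
    stop("parser did not honour the contract: expected a MetadataBundle")
  validObject(bundle)

  ds <- createDataset(sink, datasetName)
  refs <- processImage(processor, sink, dataPath, ds)
  manifest <- annotateDataset(sink, ds, bundle)
  planes <- sum(manifest@images$sizeT * manifest@images$sizeC *
                manifest@images$sizeZ)
  new("UploadReport", datasetName = datasetName, datasetId = ds@datasetId,
      imagesWritten = nrow(refs), planesWritten = as.integer(planes),
      tagsWritten = length(bundle@tags),
      kvpsWritten = nrow(bundle@kvps),
      tablesWritten = length(bundle@tables),
      warnings = as.character(attr(refs, "warnings")))
}
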