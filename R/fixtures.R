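# Synthetic multi-position plane trees with deterministic pixel content.
# Every plane in a generated tree is constant-valued at encodePixel(...),
# which is injective at small ranks, so any misplacement of a plane during
# indexing or assembly is detectable by comparing a single voxel.

#' Deterministic fixture pixel encoding
#'
#' Maps the 0-based (position, timepoint, channel, z) ranks of a plane to a
#' constant pixel value:
#' `v = ((p * 7 + t) * 5 + c) * 11 + z + 1`, reduced to the 1..max range of
#' the pixel type as `1 + (v - 1) mod max`. The value is injective for
#' small rank combinations and never 0, so genuine fixture planes are
#' always distinguishable from zero-filled gap planes.
#'
#' @param positionRank,tRank,cRank,zRank 0-based ranks (vectorised).
#' @param pixelType `"uint8"` or `"uint16"`; sets the modulo range.
#' @return Integer pixel value(s) in `1..pixelTypeMax(pixelType)`.
#' @examples
#' encodePixel(0, 0, 0, 0)  # 1
#' encodePixel(0, 1, 2, 0)  # 78
#' @export
encodePixel <- function(positionRank, tRank, cRank, zRank,
                        pixelType = "uint8") {
  stopifnot(all(positionRank >= 0), all(tRank >= 0), all(cRank >= 0),
            all(zRank >= 0))
  v <- ((as.numeric(positionRank) * 7 + tRank) * 5 + cRank) * 11 + zRank + 1
  as.integer(1 + (v - 1) %% pixelTypeMax(pixelType))
}

#' Enumerate the plane files a LayoutSpec implies
#'
#' Pure enumeration — no files are touched. One row per plane file the
#' tree would contain, with the fill value [encodePixel()] assigns it.
#' Used internally by [generateTree()] and directly when only the file
#' census of a large layout is needed.
#'
#' @param spec a [LayoutSpec-class].
#' @return `data.frame` with columns `position`, `posdir`, `file`,
#'   `prefix`, `timepoint`, `channel`, `z`, `fill`; exactly
#'   `nPositions * |timepoints| * |channels| * |z|` rows.
#' @export
enumeratePlanes <- function(spec) {
  stopifnot(is(spec, "LayoutSpec"))
  validObject(spec)
  ext <- if (spec@imageFormat == "tiff") "tif" else "png"
  g <- expand.grid(zi = seq_along(spec@zSections),
                   ci = seq_along(spec@channels),
                   ti = seq_along(spec@timepoints),
                   p = seq_len(spec@nPositions))
  data.frame(
    position = g$p,
    posdir = sprintf("pos%03d", g$p),
    file = sprintf("%s_%d_%s_%d.%s", spec@prefix,
                   spec@timepoints[g$ti], spec@channels[g$ci],
                   spec@zSections[g$zi], ext),
    prefix = spec@prefix,
    timepoint = spec@timepoints[g$ti],
    channel = spec@channels[g$ci],
    z = spec@zSections[g$zi],
    fill = encodePixel(g$p - 1L, g$ti - 1L, g$ci - 1L, g$zi - 1L,
                       spec@pixelType),
    stringsAsFactors = FALSE)
}

.writePlane <- function(path, value, h, w, format, pixelType) {
  mx <- pixelTypeMax(pixelType)
  m <- matrix(value / mx, nrow = h, ncol = w)
  if (format == "tiff") {
    tiff::writeTIFF(m, path,
                    bits.per.sample = if (pixelType == "uint16") 16L else 8L,
                    compression = "none")
  } else {
    png::writePNG(m, path)
  }
  invisible(path)
}

#' Generate a conforming plane tree on disk
#'
#' Creates `pos001` ... `pos{NNN}` subdirectories under `dest` (position
#' ids zero-padded to three digits) and, within each, one constant-valued
#' plane per (timepoint, channel, z) combination named
#' `{prefix}_{t}_{c}_{z}.{ext}`. Generation is fully deterministic: two
#' runs with the same spec produce byte-identical trees.
#'
#' @param spec a [LayoutSpec-class].
#' @param dest destination directory (created if absent; must be
#'   writable).
#' @param bundle optional [MetadataBundle-class]; when supplied,
#'   [generateMetadataFiles()] is called to place `*Acq.txt` and
#'   `*log.txt` files at the tree root.
#' @return A [FixtureManifest-class] recording every file and its
#'   expected fill value, plus the ground-truth bundle.
#' @examples
#' tree <- generateTree(LayoutSpec(1, 1, "GFP", 1), tempfile())
#' nrow(tree@planes)  # 1
#' @export
generateTree <- function(spec, dest, bundle = NULL) {
  stopifnot(is(spec, "LayoutSpec"))
  validObject(spec)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dest) || file.access(dest, 2L) != 0L)
    stop("destination not writable: ", dest)
  planes <- enumeratePlanes(spec)
  for (pd in unique(planes$posdir))
    dir.create(file.path(dest, pd), showWarnings = FALSE)
  planes$path <- file.path(dest, planes$posdir, planes$file)
  for (i in seq_len(nrow(planes)))
    .writePlane(planes$path[i], planes$fill[i], spec@planeHeight,
                spec@planeWidth, spec@imageFormat, spec@pixelType)
  acq <- NA_character_; log <- NA_character_
  if (is.null(bundle)) bundle <- MetadataBundle()
  else {
    mf <- generateMetadataFiles(dest, bundle)
    acq <- mf[["acq"]]; log <- mf[["log"]]
  }
  new("FixtureManifest", root = dest,
      planes = planes[, c("position", "path", "prefix", "timepoint",
                          "channel", "z", "fill")],
      acqPath = acq, logPath = log, bundle = bundle)
}

.assertWritable <- function(x, what, where) {
  bad <- grepl("[\t\n]", x)
  if (any(bad))
    stop(what, " must not contain tab or newline characters (", where, ")")
  invisible(x)
}

#' Write semi-structured metadata text files for a bundle
#'
#' Emits the fixed dialect the default parsers are specified against:
#' the acquisition file (`fixtureAcq.txt`) carries the description as a
#' `Description:` key-value line; the log file (`fixture_log.txt`) carries
#' a `tags:` block (one tag per line, closed by a blank line), the
#' key-value pairs one per line as `key: value`, and each table as a
#' name line followed by a tab-separated block (header row first). Files
#' are UTF-8 with LF line endings. Parsing the two files with the default
#' parsers and aggregating recovers `bundle` exactly, which requires the
#' bundle to be representable in the dialect: single-line description, no
#' tabs in tags/keys/values, table names without colons or tabs.
#'
#' @param dest directory in which to write (the tree root).
#' @param bundle the [MetadataBundle-class] to serialise.
#' @return Named character vector `c(acq = ..., log = ...)` of file paths.
#' @export
generateMetadataFiles <- function(dest, bundle) {
  stopifnot(is(bundle, "MetadataBundle"))
  validObject(bundle)
  if (!dir.exists(dest) || file.access(dest, 2L) != 0L)
    stop("destination not writable: ", dest)
  .assertWritable(bundle@description, "description", "description")
  if (grepl("\n", bundle@description))
    stop("description must be a single line to round-trip the dialect")
  .assertWritable(bundle@tags, "tags", "tag lines")
  if (any(!nzchar(trimws(bundle@tags))))
    stop("tags must be non-blank")
  if (anyDuplicated(bundle@tags))
    stop("tags must be duplicate-free to round-trip (aggregation dedups)")
  .assertWritable(bundle@kvps$key, "keys", "kvp lines")
  .assertWritable(bundle@kvps$value, "values", "kvp lines")
  if (any(grepl(":", bundle@kvps$key)))
    stop("keys must not contain ':'")
  if (any(bundle@kvps$key == "Description"))
    stop("the key 'Description' is reserved for the description field")
  tr <- function(x) identical(x, trimws(x))
  if (!tr(bundle@kvps$key) || !tr(bundle@kvps$value) ||
      !tr(bundle@description) || !tr(bundle@tags))
    stop("keys, values, tags and description must be whitespace-trimmed")
  if (any(grepl(":", names(bundle@tables))))
    stop("table names must not contain ':'")
  .assertWritable(names(bundle@tables), "table names", "table name lines")
  for (nm in names(bundle@tables)) {
    tb <- bundle@tables[[nm]]
    if (ncol(tb) < 2L || nrow(tb) < 1L)
      stop("table '", nm, "' needs >= 2 columns and >= 1 row to be ",
           "representable as a tab-separated block")
  }

  acqLines <- character()
  if (nzchar(bundle@description))
    acqLines <- paste0("Description: ", bundle@description)
  acqPath <- file.path(dest, "fixtureAcq.txt")
  writeLines(acqLines, acqPath, sep = "\n", useBytes = TRUE)

  logLines <- character()
  if (length(bundle@tags))
    logLines <- c(logLines, "tags:", bundle@tags, "")
  if (nrow(bundle@kvps))
    logLines <- c(logLines,
                  paste0(bundle@kvps$key, ": ", bundle@kvps$value), "")
  for (nm in names(bundle@tables)) {
    tb <- bundle@tables[[nm]]
    for (cl in names(tb)) .assertWritable(tb[[cl]], "table cells", nm)
    .assertWritable(names(tb), "table headers", nm)
    rows <- vapply(seq_len(nrow(tb)), function(i)
      paste(unlist(tb[i, ], use.names = FALSE), collapse = "\t"), "")
    logLines <- c(logLines, nm, paste(names(tb), collapse = "\t"), rows, "")
  }
  logPath <- file.path(dest, "fixture_log.txt")
  writeLines(logLines, logPath, sep = "\n", useBytes = TRUE)
  c(acq = acqPath, log = logPath)
}
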