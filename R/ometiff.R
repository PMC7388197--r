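# OME-TIFF output: one multi-page baseline TIFF per hypercube, with the
# OME-XML metadata block embedded in the ImageDescription tag of the first
# IFD, as the format requires. Pages are emitted in the declared
# DimensionOrder XYZCT (Z varies fastest, then C, then T). The writer
# emits uncompressed little-endian grayscale strips (one strip per page)
# so any baseline TIFF reader can consume the files; round-trip tests
# read them back with libtiff via the tiff package, an independent code
# path.

.omeXml <- function(cube, name) {
  d <- dim(cube@pixels)
  doc <- xml2::xml_new_root(
    "OME",
    xmlns = "http://www.openmicroscopy.org/Schemas/OME/2016-06")
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0", Name = name)
  px <- xml2::xml_add_child(
    img, "Pixels", ID = "Pixels:0", DimensionOrder = "XYZCT",
    Type = cube@pixelType, BigEndian = "false", Interleaved = "false",
    SignificantBits = if (cube@pixelType == "uint16") "16" else "8",
    SizeX = as.character(d[5L]), SizeY = as.character(d[4L]),
    SizeZ = as.character(d[3L]), SizeC = as.character(d[2L]),
    SizeT = as.character(d[1L]))
  for (i in seq_len(d[2L]))
    xml2::xml_add_child(px, "Channel",
                        ID = sprintf("Channel:0:%d", i - 1L),
                        Name = cube@channelNames[i],
                        SamplesPerPixel = "1")
  xml2::xml_add_child(px, "TiffData",
                      IFD = "0", FirstT = "0", FirstC = "0", FirstZ = "0",
                      PlaneCount = as.character(d[1L] * d[2L] * d[3L]))
  as.character(doc)
}

.tiffEntry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {  # SHORT: value left-justified in the 4-byte field
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a hypercube as an OME-TIFF file
#'
#' All `SizeT x SizeC x SizeZ` planes are stored in one multi-page TIFF
#' (uncompressed, little-endian, grayscale, 8- or 16-bit unsigned) with
#' the OME-XML block in the first page's ImageDescription. Plane pages
#' follow the declared `DimensionOrder="XYZCT"`: page index
#' `z + SizeZ * (c + SizeC * t)`.
#'
#' @param cube a [HyperCube-class].
#' @param path output filename (conventionally `*.ome.tiff`).
#' @param name image name recorded in the OME-XML (defaults to
#'   `pos{NNN}` from the cube's position id).
#' @return `path`, invisibly.
#' @seealso [readOmeTiff()] for the reverse operation.
#' @export
writeOmeTiff <- function(cube, path,
                         name = sprintf("pos%03d", cube@positionId)) {
  stopifnot(is(cube, "HyperCube"))
  validObject(cube)
  d <- dim(cube@pixels)
  h <- d[4L]; w <- d[5L]
  bytes <- if (cube@pixelType == "uint16") 2L else 1L
  nPages <- d[1L] * d[2L] * d[3L]
  descRaw <- c(charToRaw(enc2utf8(.omeXml(cube, name))), as.raw(0L))
  descLen <- length(descRaw)  # ASCII count includes the terminating NUL
  if (descLen %% 2L) descRaw <- c(descRaw, as.raw(0L))  # pad, uncounted

  pageBytes <- h * w * bytes
  # file layout: header | all page data | description | IFD chain
  pixOff <- 8L + (seq_len(nPages) - 1L) * pageBytes
  descOff <- 8L + nPages * pageBytes
  ifd0Off <- descOff + length(descRaw)
  nEntries <- c(11L, rep(10L, nPages - 1L))  # desc tag on first IFD only
  ifdSize <- 2L + nEntries * 12L + 4L
  ifdOff <- ifd0Off + cumsum(c(0L, ifdSize[-nPages]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0Off, con, size = 4, endian = "little")
  # pages in XYZCT order: t outermost, then c, then z
  for (t in seq_len(d[1L])) for (cc in seq_len(d[2L]))
    for (z in seq_len(d[3L])) {
      m <- cube@pixels[t, cc, z, , ]
      dim(m) <- c(h, w)
      writeBin(as.integer(t(m)), con, size = bytes, endian = "little")
    }
  writeBin(descRaw, con)
  for (p in seq_len(nPages)) {
    writeBin(nEntries[p], con, size = 2, endian = "little")
    .tiffEntry(con, 256L, 4L, 1L, w)               # ImageWidth
    .tiffEntry(con, 257L, 4L, 1L, h)               # ImageLength
    .tiffEntry(con, 258L, 3L, 1L, bytes * 8L)      # BitsPerSample
    .tiffEntry(con, 259L, 3L, 1L, 1L)              # Compression = none
    .tiffEntry(con, 262L, 3L, 1L, 1L)              # Photometric = min-is-black
    if (p == 1L)
      .tiffEntry(con, 270L, 2L, descLen, descOff)  # ImageDescription
    .tiffEntry(con, 273L, 4L, 1L, pixOff[p])       # StripOffsets
    .tiffEntry(con, 277L, 3L, 1L, 1L)              # SamplesPerPixel
    .tiffEntry(con, 278L, 4L, 1L, h)               # RowsPerStrip
    .tiffEntry(con, 279L, 4L, 1L, pageBytes)       # StripByteCounts
    .tiffEntry(con, 339L, 3L, 1L, 1L)              # SampleFormat = unsigned
    nxt <- if (p < nPages) ifdOff[p + 1L] else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an OME-TIFF file back into a hypercube
#'
#' Pixel pages are decoded with [tiff::readTIFF()] (libtiff); dimension
#' sizes, channel names and pixel type come from the embedded OME-XML.
#' Pages are de-interleaved according to the declared
#' `DimensionOrder="XYZCT"`.
#'
#' @param path an OME-TIFF file written by [writeOmeTiff()] (or any file
#'   with the same layout).
#' @param positionId position id to record in the cube; by default parsed
#'   from a `pos{NNN}` image name in the OME-XML, else 0.
#' @return A [HyperCube-class] (provenance records the source file).
#' @export
readOmeTiff <- function(path, positionId = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1L]], "description")
  if (is.null(desc)) stop("no OME-XML ImageDescription found in ", path)
  doc <- xml2::read_xml(desc)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  sz <- unname(vapply(c("SizeT", "SizeC", "SizeZ", "SizeY", "SizeX"),
                      function(a) as.integer(xml2::xml_attr(px, a)), 0L))
  type <- xml2::xml_attr(px, "Type")
  chan <- xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  if (length(pages) != sz[1L] * sz[2L] * sz[3L])
    stop("page count does not match OME-XML sizes in ", path)
  if (is.null(positionId)) {
    nm <- xml2::xml_attr(xml2::xml_find_first(doc, ".//Image"), "Name")
    positionId <- if (!is.na(nm) && grepl("^pos[0-9]+$", nm))
      as.integer(sub("^pos", "", nm)) else 0L
  }
  arr <- array(0L, dim = sz)
  i <- 0L
  for (t in seq_len(sz[1L])) for (cc in seq_len(sz[2L]))
    for (z in seq_len(sz[3L])) {
      i <- i + 1L
      arr[t, cc, z, , ] <- pages[[i]]
    }
  new("HyperCube", positionId = as.integer(positionId), pixels = arr,
      channelNames = chan, pixelType = type,
      provenance = data.frame(tRank = integer(), cRank = integer(),
                              zRank = integer(), path = character(),
                              stringsAsFactors = FALSE))
}
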