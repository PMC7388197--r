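# Discovery and validation of pos{xxx} plane trees.

.PLANE_EXTS <- c("tif", "tiff", "png")

#' Discover position subdirectories of a tree root
#'
#' Immediate subdirectories named `pos` followed by one or more digits
#' (case-insensitive, any digit width) are returned in ascending numeric
#' order; all other entries are ignored.
#'
#' @param root tree root directory.
#' @return `data.frame` with columns `positionId` (integer) and `dir`.
#' @examples
#' root <- tempfile(); dir.create(file.path(root, "pos002"), recursive = TRUE)
#' dir.create(file.path(root, "notes"))
#' scanPositions(root)  # one row, positionId 2
#' @export
scanPositions <- function(root) {
  if (!dir.exists(root)) stop("root directory not found: ", root)
  entries <- list.dirs(root, full.names = FALSE, recursive = FALSE)
  hit <- grepl("^pos[0-9]+$", entries, ignore.case = TRUE)
  ids <- as.integer(sub("^pos", "", entries[hit], ignore.case = TRUE))
  ord <- order(ids)
  data.frame(positionId = ids[ord],
             dir = file.path(root, entries[hit][ord]),
             stringsAsFactors = FALSE)
}

# Vectorised filename parsing; one row per name with ok/reason columns.
.parsePlaneNames <- function(names) {
  ext <- tolower(tools::file_ext(names))
  base <- tools::file_path_sans_ext(names)
  parts <- strsplit(base, "_", fixed = TRUE)
  n <- lengths(parts)
  out <- data.frame(file = names, ok = FALSE, prefix = NA_character_,
                    timepoint = NA_integer_, channel = NA_character_,
                    z = NA_integer_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  bad_ext <- !ext %in% .PLANE_EXTS
  out$reason[bad_ext] <- "unsupported extension"
  few <- !bad_ext & n < 4L
  out$reason[few] <- "fewer than 4 underscore-separated tokens"
  cand <- which(!bad_ext & !few)
  for (i in cand) {
    p <- parts[[i]]; k <- length(p)
    ztok <- p[k]; ctok <- p[k - 1L]; ttok <- p[k - 2L]
    if (!grepl("^[0-9]+$", ttok)) {
      out$reason[i] <- "timepoint token is not a non-negative integer"
    } else if (!grepl("^[0-9]+$", ztok)) {
      out$reason[i] <- "z token is not a non-negative integer"
    } else if (!nzchar(ctok)) {
      out$reason[i] <- "empty channel token"
    } else {
      out$ok[i] <- TRUE
      out$prefix[i] <- paste(p[seq_len(k - 3L)], collapse = "_")
      out$timepoint[i] <- as.integer(ttok)
      out$channel[i] <- ctok
      out$z[i] <- as.integer(ztok)
    }
  }
  out
}

#' Parse one plane filename against the naming convention
#'
#' The name (extension stripped) is split on underscores from the right:
#' the last token is the z-section, the second-last the channel, the
#' third-last the timepoint, and everything before — which may itself
#' contain underscores — is the prefix. Timepoint and z must be
#' non-negative integers; the channel token is kept verbatim.
#'
#' Rejection is a value, not an error: non-conforming names return a
#' `planeRejection` object carrying the reason.
#'
#' @param name a bare filename with extension (`.tif`, `.tiff` or
#'   `.png`).
#' @param path optional full path recorded in the key.
#' @return A [PlaneKey-class], or a `planeRejection` (a list with
#'   elements `file` and `reason`).
#' @examples
#' parsePlaneFilename("img_5_GFP_2.tif")          # t=5, channel GFP, z=2
#' parsePlaneFilename("my_cells_001_2_003.png")   # prefix "my_cells"
#' parsePlaneFilename("README.txt")$reason
#' @export
parsePlaneFilename <- function(name, path = "") {
  stopifnot(length(name) == 1L)
  r <- .parsePlaneNames(name)
  if (!r$ok)
    return(structure(list(file = name, reason = r$reason),
                     class = "planeRejection"))
  new("PlaneKey", prefix = r$prefix, timepoint = r$timepoint,
      channel = r$channel, z = r$z, path = as.character(path))
}

# token -> 0-based rank, numeric sort for integers, radix (locale-free)
# lexicographic otherwise
.rankTokens <- function(tokens, numeric) {
  u <- unique(tokens)
  u <- if (numeric) u[order(as.numeric(u), method = "radix")]
       else u[order(u, method = "radix")]
  stats::setNames(seq_along(u) - 1L, as.character(u))
}

#' Build a validated plane index for one position directory
#'
#' Parses every regular file in `dir` against the naming convention,
#' assigns dense 0-based rank coordinates by sorting the distinct tokens
#' (timepoint and z numerically; channel tokens numerically when all of
#' them parse as integers, lexicographically otherwise), and reports
#' missing grid cells, duplicate coordinates and rejected filenames.
#' The result is independent of filesystem enumeration order: ties are
#' broken by sorted path.
#'
#' @param positionId integer position id (from the `pos{xxx}` name).
#' @param dir the position directory.
#' @param files optional explicit character vector of filenames within
#'   `dir` (for order-invariance checks); defaults to a directory
#'   listing with hidden files skipped.
#' @return A list with elements `index` ([PlaneIndex-class]) and
#'   `report` ([ValidationReport-class]).
#' @export
buildIndex <- function(positionId, dir, files = NULL) {
  if (!dir.exists(dir)) stop("position directory not found: ", dir)
  if (is.null(files)) {
    files <- list.files(dir, all.files = FALSE, no.. = TRUE)
    files <- files[!dir.exists(file.path(dir, files))]
  }
  parsed <- .parsePlaneNames(files)
  rejected <- parsed[!parsed$ok, c("file", "reason")]
  rownames(rejected) <- NULL
  good <- parsed[parsed$ok, , drop = FALSE]

  if (nrow(good)) {
    tR <- .rankTokens(good$timepoint, numeric = TRUE)
    cR <- .rankTokens(good$channel,
                      numeric = all(grepl("^[0-9]+$", good$channel)))
    zR <- .rankTokens(good$z, numeric = TRUE)
    good$tRank <- unname(tR[as.character(good$timepoint)])
    good$cRank <- unname(cR[good$channel])
    good$zRank <- unname(zR[as.character(good$z)])
    good$path <- file.path(dir, good$file)
    # canonical order: grid coordinate, then path (makes result listing-
    # order independent and picks a deterministic winner among duplicates)
    good <- good[order(good$tRank, good$cRank, good$zRank, good$path,
                       method = "radix"), , drop = FALSE]
    key <- paste(good$tRank, good$cRank, good$zRank)
    dup <- duplicated(key)
    dupPairs <- if (any(dup)) {
      first <- good$path[match(key[dup], key)]
      data.frame(path1 = first, path2 = good$path[dup],
                 stringsAsFactors = FALSE)
    } else data.frame(path1 = character(), path2 = character(),
                      stringsAsFactors = FALSE)
    kept <- good[!dup, , drop = FALSE]
    extents <- c(length(tR), length(cR), length(zR))
    grid <- expand.grid(zRank = seq_len(extents[3L]) - 1L,
                        cRank = seq_len(extents[2L]) - 1L,
                        tRank = seq_len(extents[1L]) - 1L)
    gkey <- paste(grid$tRank, grid$cRank, grid$zRank)
    miss <- grid[!gkey %in% key, c("tRank", "cRank", "zRank")]
    miss <- miss[order(miss$tRank, miss$cRank, miss$zRank), , drop = FALSE]
  } else {
    tR <- cR <- zR <- stats::setNames(integer(), character())
    kept <- data.frame(path = character(), file = character(),
                       prefix = character(), timepoint = integer(),
                       channel = character(), z = integer(),
                       tRank = integer(), cRank = integer(),
                       zRank = integer(), stringsAsFactors = FALSE)
    dupPairs <- data.frame(path1 = character(), path2 = character(),
                           stringsAsFactors = FALSE)
    extents <- c(0L, 0L, 0L)
    miss <- data.frame(tRank = integer(), cRank = integer(),
                       zRank = integer())
  }
  rownames(kept) <- NULL
  rownames(miss) <- NULL
  idx <- new("PlaneIndex", positionId = as.integer(positionId), dir = dir,
             tRanks = tR, cRanks = cR, zRanks = zR,
             planes = kept[, c("path", "file", "prefix", "timepoint",
                               "channel", "z", "tRank", "cRank", "zRank")],
             extents = as.integer(extents))
  rep <- new("ValidationReport", missing = miss, duplicates = dupPairs,
             rejected = rejected,
             isComplete = nrow(miss) == 0L && nrow(dupPairs) == 0L)
  list(index = idx, report = rep)
}
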