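# Semi-structured metadata extraction. Three line-level rules — colon
# key-value pairs, a `tags:` block, tab-separated table blocks — are
# declared in a configuration record (parserRules) so lab-specific
# dialects can override the patterns without code changes. Precedence
# within a file: the tag block is segmented first, then table blocks
# (including their name lines), and the key-value rule applies to the
# remaining lines only.

#' Parser rule configuration
#'
#' The patterns and thresholds the default extractors use. Override
#' individual entries to adapt to a lab-specific dialect.
#'
#' @param tagHeader regex (case-insensitive) opening a tag block.
#' @param descriptionKey the key whose value becomes the bundle
#'   description (consumed from the key-value pairs).
#' @param acqGlob,logGlob filename globs locating the two metadata files
#'   at a tree root.
#' @param tableMinLines minimum consecutive tab-separated lines that form
#'   a table block.
#' @return A named list of class `parserRules`.
#' @export
parserRules <- function(tagHeader = "^tags:[[:space:]]*$",
                        descriptionKey = "Description",
                        acqGlob = "*Acq.txt", logGlob = "*log.txt",
                        tableMinLines = 2L) {
  structure(list(tagHeader = tagHeader, descriptionKey = descriptionKey,
                 acqGlob = acqGlob, logGlob = logGlob,
                 tableMinLines = as.integer(tableMinLines)),
            class = "parserRules")
}

# Normalise text input to a character vector of lines, preserving blank
# lines (strsplit("") would drop them).
.asLines <- function(text) {
  if (!length(text)) return(character())
  unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE),
         use.names = FALSE)
}

#' Parse colon-delimited key-value lines
#'
#' Line-local rule: every line containing a colon is split at the FIRST
#' colon; key and value are whitespace-trimmed; lines without a colon
#' yield nothing; input order is preserved. Splitting at the first colon
#' keeps clock times (`Start time: 12:30:00`) intact as values.
#'
#' @param text a character vector of lines, or a single string with
#'   embedded newlines.
#' @return Two-column character `data.frame` (`key`, `value`).
#' @examples
#' parseKvpLines("Microscope: Nikon Ti")
#' parseKvpLines("Start time: 12:30:00")$value  # "12:30:00"
#' @export
parseKvpLines <- function(text) {
  lines <- .asLines(text)
  hit <- grepl(":", lines, fixed = TRUE)
  m <- regexpr(":", lines[hit], fixed = TRUE)
  data.frame(key = trimws(substr(lines[hit], 1L, m - 1L)),
             value = trimws(substr(lines[hit], m + 1L,
                                   nchar(lines[hit]))),
             stringsAsFactors = FALSE)
}

# Locate the tag block: (header line index, tag line indices) or NULL.
.tagBlock <- function(lines, rules) {
  hdr <- grep(rules$tagHeader, lines, ignore.case = TRUE)
  if (!length(hdr)) return(NULL)
  hdr <- hdr[1L]
  end <- hdr
  n <- length(lines)
  while (end < n && nzchar(trimws(lines[end + 1L]))) end <- end + 1L
  list(header = hdr,
       body = if (end > hdr) (hdr + 1L):end else integer())
}

# Locate table blocks: list of (name line or NA, header line, row lines,
# ragged flag), scanning only `eligible` line indices.
.tableBlocks <- function(lines, eligible, rules) {
  hasTab <- grepl("\t", lines, fixed = TRUE) & eligible
  r <- rle(hasTab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < rules$tableMinLines) next
    idx <- starts[i]:ends[i]
    tabCounts <- vapply(lines[idx], function(l)
      lengths(regmatches(l, gregexpr("\t", l, fixed = TRUE))), 0L,
      USE.NAMES = FALSE)
    ragged <- length(unique(tabCounts)) != 1L
    nameLine <- NA_integer_
    prev <- idx[1L] - 1L
    if (prev >= 1L && eligible[prev] && nzchar(trimws(lines[prev])) &&
        !grepl("\t", lines[prev], fixed = TRUE))
      nameLine <- prev
    blocks[[length(blocks) + 1L]] <-
      list(name = nameLine, lines = idx, ragged = ragged)
  }
  blocks
}

#' Extract tag labels from a tag block
#'
#' Lines inside a block opened by a `tags:` header line
#' (case-insensitive) and closed by the first blank line are returned as
#' individual trimmed tags. Files without such a block yield no tags.
#'
#' @param text lines or a single newline-joined string.
#' @param rules a [parserRules()] record.
#' @return Character vector of tags (duplicates preserved here; the
#'   aggregation stage removes them).
#' @examples
#' parseTags(c("tags:", "timelapse", "yeast", "", "other: stuff"))
#' @export
parseTags <- function(text, rules = parserRules()) {
  lines <- .asLines(text)
  blk <- .tagBlock(lines, rules)
  if (is.null(blk)) character() else trimws(lines[blk$body])
}

#' Extract named tables from tab-separated blocks
#'
#' A table block is a maximal run of at least `tableMinLines` consecutive
#' lines, each containing at least one tab, with a constant tab count.
#' The non-blank, non-tabbed line immediately preceding a block (if any)
#' is taken as its name; otherwise the block is named `table_{k}` by
#' 1-based occurrence among the unnamed blocks. The first line of a block
#' is its header row. Ragged blocks (varying cell counts) are skipped,
#' with a warning naming the offending lines.
#'
#' @inheritParams parseTags
#' @return Named list of character `data.frame`s.
#' @export
parseTables <- function(text, rules = parserRules()) {
  lines <- .asLines(text)
  eligible <- rep(TRUE, length(lines))
  tb <- .tagBlock(lines, rules)
  if (!is.null(tb)) eligible[c(tb$header, tb$body)] <- FALSE
  blocks <- .tableBlocks(lines, eligible, rules)
  out <- list()
  unnamed <- 0L
  for (b in blocks) {
    if (b$ragged) {
      warning("skipping ragged table block at lines ",
              b$lines[1L], "-", b$lines[length(b$lines)])
      next
    }
    nm <- if (is.na(b$name)) {
      unnamed <- unnamed + 1L
      sprintf("table_%d", unnamed)
    } else trimws(lines[b$name])
    cells <- strsplit(lines[b$lines], "\t", fixed = TRUE)
    # cells per line = tab count + 1; strsplit drops trailing empties, pad
    ncol <- lengths(regmatches(lines[b$lines[1L]],
                               gregexpr("\t", lines[b$lines[1L]],
                                        fixed = TRUE))) + 1L
    cells <- lapply(cells, function(x) c(x, rep("", ncol - length(x))))
    df <- as.data.frame(do.call(rbind, cells[-1L]),
                        stringsAsFactors = FALSE)
    names(df) <- cells[[1L]]
    rownames(df) <- NULL
    out[[length(out) + 1L]] <- df
    names(out)[length(out)] <- nm
  }
  out
}

#' Merge metadata bundles
#'
#' Combines parser outputs into one record: descriptions are joined with
#' a blank line (empty ones skipped); tags become the order-preserving
#' union; key-value pairs are concatenated in input order with exact
#' duplicate pairs removed (first occurrence kept); tables are
#' concatenated with name collisions disambiguated by suffixing `_2`,
#' `_3`, ...
#'
#' @param bundles a non-empty list of [MetadataBundle-class] objects.
#' @return A single [MetadataBundle-class].
#' @examples
#' a <- MetadataBundle(tags = c("a", "b"))
#' b <- MetadataBundle(tags = c("b", "c"))
#' metaTags(aggregateBundles(list(a, b)))  # "a" "b" "c"
#' @export
aggregateBundles <- function(bundles) {
  stopifnot(length(bundles) >= 1L,
            all(vapply(bundles, is, logical(1), "MetadataBundle")))
  desc <- vapply(bundles, slot, "", "description")
  desc <- paste(desc[nzchar(desc)], collapse = "\n\n")
  tags <- unique(unlist(lapply(bundles, slot, "tags"), use.names = FALSE))
  if (is.null(tags)) tags <- character()
  kv <- do.call(rbind, lapply(bundles, slot, "kvps"))
  kv <- kv[!duplicated(paste0(kv$key, "\r", kv$value)), , drop = FALSE]
  rownames(kv) <- NULL
  tabs <- list()
  for (b in bundles) for (nm in names(b@tables)) {
    use <- nm
    k <- 2L
    while (use %in% names(tabs)) {
      use <- sprintf("%s_%d", nm, k)
      k <- k + 1L
    }
    tabs[[use]] <- b@tables[[nm]]
  }
  MetadataBundle(description = desc, tags = tags, kvps = kv, tables = tabs)
}

# ---- parser classes -------------------------------------------------------

#' Metadata parser classes
#'
#' @description
#' `MetadataParser` is the virtual base of the pluggable parser
#' hierarchy; any subclass providing an [extractMetadata()] method is
#' substitutable at runtime.
#'
#' `LogMetadataParser` and `AcqMetadataParser` are the two default leaf
#' parsers. Both apply the full rule set (tag block, table blocks,
#' key-value lines, description key) to a single text file; they differ
#' in which file the aggregator hands them (`*log.txt` vs `*Acq.txt`).
#'
#' `MetadataAggregator` is the default top-level parser: pointed at a
#' tree root, it locates the acquisition and log files by glob, runs the
#' two leaf parsers and merges their outputs with [aggregateBundles()].
#'
#' `FunctionParser` adapts a plain function `function(source) -> bundle`
#' to the contract (used by the plug-in loader).
#'
#' @slot rules a [parserRules()] record.
#' @slot fun (`FunctionParser`) the wrapped function.
#' @aliases MetadataParser-class LogMetadataParser-class
#'   AcqMetadataParser-class MetadataAggregator-class
#'   FunctionParser-class
#' @name MetadataParser-class
#' @exportClass MetadataParser
setClass("MetadataParser", representation("VIRTUAL"))

#' @rdname MetadataParser-class
#' @exportClass LogMetadataParser
setClass("LogMetadataParser", contains = "MetadataParser",
         representation(rules = "list"))

#' @rdname MetadataParser-class
#' @exportClass AcqMetadataParser
setClass("AcqMetadataParser", contains = "MetadataParser",
         representation(rules = "list"))

#' @rdname MetadataParser-class
#' @exportClass MetadataAggregator
setClass("MetadataAggregator", contains = "MetadataParser",
         representation(rules = "list"))

#' @rdname MetadataParser-class
#' @exportClass FunctionParser
setClass("FunctionParser", contains = "MetadataParser",
         representation(fun = "function"))

#' @rdname MetadataParser-class
#' @param rules a [parserRules()] record.
#' @export
LogMetadataParser <- function(rules = parserRules())
  new("LogMetadataParser", rules = unclass(rules))

#' @rdname MetadataParser-class
#' @export
AcqMetadataParser <- function(rules = parserRules())
  new("AcqMetadataParser", rules = unclass(rules))

#' @rdname MetadataParser-class
#' @export
MetadataAggregator <- function(rules = parserRules())
  new("MetadataAggregator", rules = unclass(rules))

# Full single-file extraction shared by the two leaf parsers.
.extractFile <- function(path, rules) {
  if (!file.exists(path) || dir.exists(path))
    stop("metadata source not readable: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rl <- do.call(parserRules, rules)
  tags <- parseTags(lines, rl)
  tables <- parseTables(lines, rl)
  # key-value scan over lines not claimed by the tag block or any table
  # block (including table name lines)
  eligible <- rep(TRUE, length(lines))
  tb <- .tagBlock(lines, rl)
  if (!is.null(tb)) eligible[c(tb$header, tb$body)] <- FALSE
  for (b in .tableBlocks(lines, eligible, rl))
    eligible[c(b$lines, if (!is.na(b$name)) b$name)] <- FALSE
  kv <- parseKvpLines(lines[eligible])
  desc <- ""
  di <- which(kv$key == rl$descriptionKey)
  if (length(di)) {
    desc <- kv$value[di[1L]]
    kv <- kv[-di[1L], , drop = FALSE]
    rownames(kv) <- NULL
  }
  MetadataBundle(description = desc, tags = tags, kvps = kv,
                 tables = tables)
}

#' @describeIn extractMetadata default log-file parsing: full rule set
#'   applied to one text file.
setMethod("extractMetadata", "LogMetadataParser",
          function(parser, source, ...) .extractFile(source, parser@rules))

#' @describeIn extractMetadata default acquisition-file parsing
#'   (identical rule set, conventionally pointed at the `*Acq.txt` file).
setMethod("extractMetadata", "AcqMetadataParser",
          function(parser, source, ...) .extractFile(source, parser@rules))

#' @describeIn extractMetadata tree-root aggregation: locates the
#'   acquisition and log files by glob at `source` (a directory), parses
#'   each with its leaf parser, and merges. Missing files contribute
#'   empty bundles.
setMethod("extractMetadata", "MetadataAggregator",
          function(parser, source, ...) {
  if (!dir.exists(source))
    stop("metadata source must be a tree root directory: ", source)
  rl <- do.call(parserRules, parser@rules)
  findOne <- function(glob) {
    hits <- Sys.glob(file.path(source, glob))
    hits <- hits[!dir.exists(hits)]
    if (length(hits)) sort(hits)[1L] else NA_character_
  }
  acq <- findOne(rl$acqGlob)
  log <- findOne(rl$logGlob)
  parts <- list()
  if (!is.na(acq))
    parts[[length(parts) + 1L]] <- extractMetadata(AcqMetadataParser(rl), acq)
  if (!is.na(log))
    parts[[length(parts) + 1L]] <- extractMetadata(LogMetadataParser(rl), log)
  if (!length(parts)) MetadataBundle() else aggregateBundles(parts)
})

#' @describeIn extractMetadata adapter: calls the wrapped function and
#'   checks it honoured the four-field contract.
setMethod("extractMetadata", "FunctionParser",
          function(parser, source, ...) {
  out <- parser@fun(source)
  if (!is(out, "MetadataBundle"))
    stop("custom parser must return a MetadataBundle")
  validObject(out)
  out
})
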