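test_that("key-value extraction splits at the first colon and trims", {
  kv <- parseKvpLines("Microscope: Nikon Ti")
  expect_identical(kv$key, "Microscope")
  expect_identical(kv$value, "Nikon Ti")
  # clock times survive because only the FIRST colon splits
  kv2 <- parseKvpLines("Start time: 12:30:00")
  expect_identical(kv2$value, "12:30:00")
  expect_identical(nrow(parseKvpLines("no delimiter here")), 0L)
  # order preserved; line-local (permuting lines permutes output)
  lines <- c("b: 2", "plain", "a: 1")
  expect_identical(parseKvpLines(lines)$key, c("b", "a"))
  expect_identical(parseKvpLines(rev(lines))$key, c("a", "b"))
  expect_identical(parseKvpLines("  padded  :  v  "),
                   data.frame(key = "padded", value = "v",
                              stringsAsFactors = FALSE))
})

test_that("tag blocks are delimited by a tags: header and the first blank line", {
  txt <- c("preamble", "tags:", " timelapse ", "yeast", "", "after: x")
  expect_identical(parseTags(txt), c("timelapse", "yeast"))
  expect_identical(parseTags("no block here"), character())
  # case-insensitive header; duplicates preserved at this stage
  expect_identical(parseTags(c("TAGS:", "a", "a", "")), c("a", "a"))
  # block at end of file closes implicitly
  expect_identical(parseTags(c("tags:", "solo")), "solo")
})

test_that("table blocks are maximal constant-tab runs with optional name lines", {
  txt <- c("growth", "strain\tod", "FY4\t0.31", "FY5\t0.29", "")
  tb <- parseTables(txt)
  expect_identical(names(tb), "growth")
  expect_identical(tb$growth,
                   data.frame(strain = c("FY4", "FY5"), od = c("0.31", "0.29"),
                              stringsAsFactors = FALSE))
  # no tabs -> no tables
  expect_identical(parseTables(c("a", "b: c")), list())
  # two unnamed blocks (preceded by blanks) get table_1, table_2
  txt2 <- c("", "a\tb", "1\t2", "", "c\td", "3\t4")
  tb2 <- parseTables(txt2)
  expect_identical(names(tb2), c("table_1", "table_2"))
  # ragged blocks are skipped with a warning, not fatal
  expect_warning(tb3 <- parseTables(c("x\ty", "1\t2\t3", "ok\tstill")),
                 "ragged")
  expect_identical(tb3, list())
  # a single tabbed line is not a block
  expect_identical(parseTables("lonely\tline"), list())
})

test_that("full-file extraction segments tags and tables before the kvp scan", {
  d <- tempfile("meta"); dir.create(d)
  f <- file.path(d, "runlog.txt")
  writeLines(c("tags:", "yeast", "", "Description: diel run",
               "Microscope: Nikon Ti", "", "exposure", "ch\tms",
               "1\t50"), f)
  b <- extractMetadata(LogMetadataParser(), f)
  expect_identical(description(b), "diel run")
  expect_identical(metaTags(b), "yeast")
  # the tag header and table lines never leak into the kvps
  expect_identical(kvps(b)$key, "Microscope")
  expect_identical(names(metaTables(b)), "exposure")
})

test_that("the contract shape always holds, even for empty input", {
  f <- tempfile(fileext = ".txt"); file.create(f)
  b <- extractMetadata(LogMetadataParser(), f)
  expect_s4_class(b, "MetadataBundle")
  expect_identical(description(b), "")
  expect_identical(metaTags(b), character())
  expect_identical(nrow(kvps(b)), 0L)
  expect_identical(metaTables(b), list())
  expect_error(extractMetadata(LogMetadataParser(), tempfile()),
               "not readable")
})

test_that("aggregation merges per the stated rules", {
  a <- MetadataBundle(description = "first", tags = c("a", "b"),
                      kvps = c(k = "1"))
  b <- MetadataBundle(description = "second", tags = c("b", "c"),
                      kvps = c(k = "1"))
  m <- aggregateBundles(list(a, b))
  expect_identical(description(m), "first\n\nsecond")
  expect_identical(metaTags(m), c("a", "b", "c"))
  expect_identical(nrow(kvps(m)), 1L)  # exact duplicate removed
  # same key, different values: both kept
  m2 <- aggregateBundles(list(MetadataBundle(kvps = c(k = "1")),
                              MetadataBundle(kvps = c(k = "2"))))
  expect_identical(kvps(m2)$value, c("1", "2"))
  # identity on a single bundle
  expect_identical(aggregateBundles(list(a)), a)
  # table name collisions get numeric suffixes
  t1 <- MetadataBundle(tables = list(tbl = data.frame(a = "1", b = "2")))
  m3 <- aggregateBundles(list(t1, t1, t1))
  expect_identical(names(metaTables(m3)), c("tbl", "tbl_2", "tbl_3"))
})

test_that("aggregation is associative on fixture bundles", {
  a <- MetadataBundle(description = "A", tags = c("x", "y"),
                      kvps = c(p = "1"),
                      tables = list(t = data.frame(a = "1", b = "2")))
  b <- MetadataBundle(tags = c("y", "z"), kvps = c(p = "1", q = "2"))
  c3 <- MetadataBundle(description = "C",
                       tables = list(t = data.frame(a = "3", b = "4")))
  left <- aggregateBundles(list(aggregateBundles(list(a, b)), c3))
  right <- aggregateBundles(list(a, aggregateBundles(list(b, c3))))
  expect_identical(left, right)
})

test_that("custom parsers are substitutable and the tree aggregator finds both files", {
  fixed <- MetadataBundle(description = "injected", tags = "custom")
  fp <- new("FunctionParser", fun = function(source) fixed)
  expect_identical(extractMetadata(fp, "ignored"), fixed)
  # a parser that violates the contract is rejected
  bad <- new("FunctionParser", fun = function(source) list(tags = "x"))
  expect_error(extractMetadata(bad, "ignored"), "MetadataBundle")

  tr <- makeTree(LayoutSpec(1, 1, "1", 1, planeHeight = 4L, planeWidth = 4L),
                 bundle = richBundle())
  got <- extractMetadata(MetadataAggregator(), tr@root)
  expect_identical(got, richBundle())
  # description arrives via the acquisition file, the rest via the log
  acq <- extractMetadata(AcqMetadataParser(), tr@acqPath)
  expect_identical(description(acq), description(richBundle()))
  expect_identical(metaTags(acq), character())
})
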