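test_that("a fixture grid assembles into a cube of the right shape and content", {
  tr <- makeTree()
  pos <- scanPositions(tr@root)
  for (i in seq_len(nrow(pos))) {
    bi <- buildIndex(pos$positionId[i], pos$dir[i])
    cube <- assembleCube(bi$index)
    expect_identical(unname(extents(cube)), c(3L, 3L, 1L, 16L, 16L))
    expect_identical(channelNames(cube), c("1", "2", "3"))
    # full-volume oracle: every cell constant at the encoded value,
    # verified against an independent re-read of each source file
    for (r in seq_len(nrow(bi$index@planes))) {
      p <- bi$index@planes[r, ]
      block <- pixelArray(cube)[p$tRank + 1L, p$cRank + 1L, p$zRank + 1L, , ]
      src <- tiff::readTIFF(p$path, as.is = TRUE)
      expect_true(all(block == as.integer(src)))
      expect_identical(unique(as.vector(block)),
                       encodePixel(i - 1L, p$tRank, p$cRank, p$zRank))
    }
  }
})

test_that("a single-plane index assembles to a (1,1,1,H,W) identity cube", {
  tr <- makeTree(LayoutSpec(1, 1, "GFP", 1, planeHeight = 5L,
                            planeWidth = 7L))
  bi <- buildIndex(1L, file.path(tr@root, "pos001"))
  cube <- assembleCube(bi$index)
  expect_identical(unname(extents(cube)), c(1L, 1L, 1L, 5L, 7L))
  src <- tiff::readTIFF(bi$index@planes$path[1], as.is = TRUE)
  expect_identical(as.vector(cube@pixels[1, 1, 1, , ]), as.vector(src))
})

test_that("voxel conservation: cube sum equals the sum over source planes", {
  tr <- makeTree(LayoutSpec(1, 1:2, c("1", "2"), 1:2, planeHeight = 6L,
                            planeWidth = 6L))
  bi <- buildIndex(1L, file.path(tr@root, "pos001"))
  cube <- assembleCube(bi$index)
  planeSum <- sum(vapply(bi$index@planes$path, function(p)
    sum(tiff::readTIFF(p, as.is = TRUE)), 0))
  expect_identical(sum(as.numeric(pixelArray(cube))), planeSum)
})

test_that("assembly is order-independent over plane-map insertion order", {
  tr <- makeTree(LayoutSpec(1, 1:2, c("1", "2"), 1:2, planeHeight = 4L,
                            planeWidth = 4L))
  bi <- buildIndex(1L, file.path(tr@root, "pos001"))
  ref <- assembleCube(bi$index)
  set.seed(7)
  for (i in 1:3) {
    shuffled <- bi$index
    shuffled@planes <- shuffled@planes[sample(nrow(shuffled@planes)), ]
    expect_identical(assembleCube(shuffled)@pixels, ref@pixels)
  }
})

test_that("missing cells abort under 'error' and become zero planes under 'zero'", {
  tr <- makeTree(LayoutSpec(1, 1:2, c("1", "2"), 1, planeHeight = 4L,
                            planeWidth = 4L))
  d <- file.path(tr@root, "pos001")
  unlink(file.path(d, "img_1_2_1.tif"))
  bi <- buildIndex(1L, d)
  expect_error(assembleCube(bi$index), "missing grid cell")
  expect_error(assembleCube(bi$index), "t=0,c=1,z=0")  # cells are listed
  cube <- assembleCube(bi$index, fillPolicy = "zero")
  expect_true(all(cube@pixels[1, 2, 1, , ] == 0L))
  # zero-fill adds nothing to the voxel sum
  planeSum <- sum(vapply(bi$index@planes$path, function(p)
    sum(tiff::readTIFF(p, as.is = TRUE)), 0))
  expect_identical(sum(as.numeric(cube@pixels)), planeSum)
})

test_that("mixed plane shapes or bit depths are an error naming both files", {
  tr <- makeTree(LayoutSpec(1, 1:2, "1", 1, planeHeight = 4L,
                            planeWidth = 4L))
  d <- file.path(tr@root, "pos001")
  # overwrite one plane with a different shape
  tiff::writeTIFF(matrix(0.5, 3, 3), file.path(d, "img_2_1_1.tif"),
                  bits.per.sample = 8L)
  bi <- buildIndex(1L, d)
  err <- tryCatch(assembleCube(bi$index), error = conditionMessage)
  expect_match(err, "img_1_1_1\\.tif")
  expect_match(err, "img_2_1_1\\.tif")
  # and a different bit depth
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(d, "img_2_1_1.tif"),
                  bits.per.sample = 16L)
  bi2 <- buildIndex(1L, d)
  expect_error(assembleCube(bi2$index), "pixel types")
})

test_that("the default processor yields one image reference per position, ascending", {
  tr <- makeTree()
  sink <- LocalSink(tempfile("sink"))
  ds <- createDataset(sink, "proc")
  refs <- processImage(DefaultImageProcessor(), sink, tr@root, ds)
  expect_identical(refs$positionId, 1:3)
  expect_identical(refs$file, sprintf("pos%03d.ome.tiff", 1:3))
  expect_length(attr(refs, "warnings"), 0L)
  # vacuous input: no pos directories -> empty refs plus a warning
  emptyTree <- tempfile("none"); dir.create(emptyTree)
  ds2 <- createDataset(sink, "empty")
  refs2 <- processImage(DefaultImageProcessor(), sink, emptyTree, ds2)
  expect_identical(nrow(refs2), 0L)
  expect_match(attr(refs2, "warnings"), "no pos")
})

test_that("a custom processor honouring the contract is substitutable", {
  tr <- makeTree(LayoutSpec(1, 1, "1", 1, planeHeight = 4L, planeWidth = 4L))
  sink <- LocalSink(tempfile("sink"))
  counter <- new.env(); counter$calls <- 0L
  fp <- new("FunctionProcessor", fun = function(broker, path, dataset) {
    counter$calls <- counter$calls + 1L
    data.frame(positionId = integer(), file = character())
  })
  ds <- createDataset(sink, "custom")
  refs <- processImage(fp, sink, tr@root, ds)
  expect_identical(counter$calls, 1L)
  expect_identical(nrow(refs), 0L)
})
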