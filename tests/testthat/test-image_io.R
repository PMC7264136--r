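# Stack reading (PNG/TIFF/BMP/DICOM), blank-slice trimming, pairing and
# report serialization.

test_that("a PNG slice directory reads back identically", {
  dir <- withr::local_tempdir()
  st <- renderPhantom(phantomSpec(sliceDims = c(64L, 64L), nSlices = 4L))
  # quantize to whole intensities so the 8-bit write is lossless
  st@slices <- round(st@slices)
  writeStack(st, dir)
  back <- readStack(dir)
  expect_equal(nSlices(back), 4)
  expect_equal(sliceDims(back), c(64L, 64L))
  expect_equal(back@slices, st@slices)
})

test_that("slice files sort naturally, not lexicographically", {
  dir <- withr::local_tempdir()
  vals <- c(10, 30, 50, 70, 90, 110, 130, 150, 170, 190, 210, 230)
  for (i in seq_along(vals))
    png::writePNG(matrix(vals[i] / 255, 16, 16),
                  file.path(dir, sprintf("slice%d.png", i - 1)))
  st <- readStack(dir)   # slice2 must come before slice10
  got <- vapply(seq_len(12) - 1L, function(i) getSlice(st, i)[1, 1],
                numeric(1))
  expect_equal(got, vals)
})

test_that("16-bit PNG rescales its full range onto [0, 255]", {
  dir <- withr::local_tempdir()
  m <- matrix(seq(0, 1, length.out = 256), 16, 16)
  png::writePNG(m, file.path(dir, "s0.png"), dpi = NULL)
  st <- readStack(dir)
  expect_equal(max(st@slices), 255, tolerance = 1e-6)
})

test_that("mixed dimensions and empty directories are rejected", {
  dir <- withr::local_tempdir()
  expect_error(readStack(dir), "no input")
  png::writePNG(matrix(0.5, 64, 64), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 32, 32), file.path(dir, "b.png"))
  expect_error(readStack(dir), "inconsistent")
  expect_error(readStack(file.path(dir, "missing")), "directory")
})

test_that("color input collapses through luma and gray is untouched", {
  dir <- withr::local_tempdir()
  rgb <- array(0, dim = c(16, 16, 3))
  rgb[, , 1] <- 1                    # pure red
  png::writePNG(rgb, file.path(dir, "s.png"))
  st <- readStack(dir)
  expect_equal(st@slices[1, 1, 1], 0.299 * 255, tolerance = 1e-6)
  gray <- matrix(round(seq(0, 255, length.out = 256)) / 255, 16, 16)
  dir2 <- withr::local_tempdir()
  png::writePNG(gray, file.path(dir2, "s.png"))
  expect_equal(readStack(dir2)@slices[, , 1], gray * 255,
               tolerance = 1e-9)
})

test_that("8-bit and 24-bit BMP slices read correctly", {
  dir <- withr::local_tempdir()
  m <- matrix(round(seq(0, 255, length.out = 300))[1:300], 15, 20)
  writeTestBMP8(m, file.path(dir, "s1.bmp"))
  st <- readStack(dir)
  expect_equal(st@slices[, , 1], m)
  # 24-bit: gray pixels must reproduce, color goes through luma
  rgb <- array(0, dim = c(16, 16, 3))
  rgb[, , 1] <- 120; rgb[, , 2] <- 120; rgb[, , 3] <- 120
  rgb[3, 4, ] <- c(255, 0, 0)
  dir2 <- withr::local_tempdir()
  writeTestBMP24(rgb, file.path(dir2, "s1.bmp"))
  st2 <- readStack(dir2)
  expect_equal(st2@slices[1, 1, 1], 120)
  expect_equal(st2@slices[3, 4, 1], 0.299 * 255, tolerance = 1e-9)
})

test_that("DICOM series order by instance and rescale per stack", {
  dir <- withr::local_tempdir()
  a <- matrix(0, 16, 16);  a[5, 5] <- 1000     # instance 2
  b <- matrix(0, 16, 16);  b[2, 2] <- 500      # instance 1
  writeTestDICOM(a, file.path(dir, "z_second.dcm"), instance = 2)
  writeTestDICOM(b, file.path(dir, "a_first.dcm"), instance = 1)
  st <- readStack(dir)
  # instance order wins over file names
  expect_equal(which(st@slices[, , 1] > 0), 2L + 1L * 16L)
  # per-stack min-max: the global maximum maps to 255, the half maximum
  # in the other slice to 127.5
  expect_equal(st@slices[5, 5, 2], 255)
  expect_equal(st@slices[2, 2, 1], 127.5)
  expect_equal(st@pixelSpacing, 0.2)
})

test_that("DICOM rescale slope and intercept are applied", {
  dir <- withr::local_tempdir()
  m <- matrix(c(0, 100), 16, 16)
  writeTestDICOM(m, file.path(dir, "s.dcm"), slope = 2, intercept = -100)
  one <- readDICOMSlice(file.path(dir, "s.dcm"))
  expect_equal(sort(unique(as.vector(one$pixels))), c(-100, 100))
})

test_that("blank-slice trimming removes only leading and trailing runs", {
  blank <- matrix(0, 16, 16)
  solid <- matrix(100, 16, 16)
  st <- imageStack(c(rep(list(blank), 3), rep(list(solid), 5),
                     rep(list(blank), 2)))
  tr <- trimBlankSlices(st)
  expect_equal(nSlices(tr), 5)
  # idempotent
  expect_equal(trimBlankSlices(tr)@slices, tr@slices)
  # interior blanks are retained
  st2 <- imageStack(list(solid, blank, solid))
  expect_equal(nSlices(trimBlankSlices(st2)), 3)
  # no blanks: identity
  st3 <- imageStack(rep(list(solid), 4))
  expect_equal(trimBlankSlices(st3)@slices, st3@slices)
  expect_error(trimBlankSlices(imageStack(rep(list(blank), 3))),
               "empty after trim")
})

test_that("pairing validates counts and labels", {
  off <- imageStack(array(50, c(16, 16, 3)), marState = "off",
                    voxelMM = 0.2, kvp = 70)
  on <- imageStack(array(50, c(16, 16, 3)), marState = "on",
                   voxelMM = 0.2, kvp = 70)
  expect_s4_class(pairStacks(off, on), "StackPair")
  short <- imageStack(array(50, c(16, 16, 2)), marState = "on",
                      voxelMM = 0.2, kvp = 70)
  expect_error(pairStacks(off, short), "3 vs 2")
  wrongVox <- imageStack(array(50, c(16, 16, 3)), marState = "on",
                         voxelMM = 0.3, kvp = 70)
  expect_error(pairStacks(off, wrongVox), "label")
  expect_error(pairStacks(on, off), "marState")
})

test_that("reports round-trip exactly through CSV and JSON", {
  sim <- makePair(phantomSpec(nSlices = 3L), kOff = 7, kOn = 3, seed = 6)
  rep <- analyzePair(sim, phantomEdgeParams())
  for (ext in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    writeReport(rep, f)
    expectReportsEqual(readReport(f), rep)
  }
  # a non-terminating ratio survives textual round trip bit-exactly
  rr <- rep
  rr@offCounts@counts <- c(3L, 4L, 2L)
  rr@onCounts@counts <- c(1L, 2L, 1L)
  rr@perSliceDiff <- c(2L, 2L, 1L)
  rr@totalOff <- 9L; rr@totalOn <- 4L
  rr@reductionRatioPct <- 100 * 5 / 9
  rr@meanDiff <- 5 / 3; rr@sdDiff <- sd(c(2, 2, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeReport(rr, f)
  expect_identical(readReport(f)@reductionRatioPct, 100 * 5 / 9)
})

test_that("edge maps write as binary PNGs with optional overlay", {
  em <- detectEdges(diskImage(32, 6), phantomEdgeParams())
  f <- withr::local_tempfile(fileext = ".png")
  writeEdgeMap(em, f)
  back <- png::readPNG(f)
  expect_true(all(back %in% c(0, 1)))
  expect_equal(back == 1, em@pixels)
  f2 <- withr::local_tempfile(fileext = ".png")
  writeEdgeMap(em, f2, baseline = diskImage(32, 6))
  expect_true(file.exists(f2))
  expect_error(writeEdgeMap(em, f2, baseline = matrix(0, 4, 4)), "dimensions")
})
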