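# Fixture builders: tiny images and on-the-fly BMP/DICOM writers so no
# binary files live in the repository.

randomGrid <- function(n, m = n, lo = 0, hi = 255) {
  matrix(stats::runif(n * m, lo, hi), n, m)
}

diskImage <- function(n, radius, value = 200, bg = 0,
                      center = c((n + 1) / 2, (n + 1) / 2)) {
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  ifelse((r - center[1])^2 + (c - center[2])^2 <= radius^2, value, bg)
}

# uncompressed 8-bit grayscale BMP (bottom-up, gray palette)
writeTestBMP8 <- function(mat, path) {
  h <- nrow(mat); w <- ncol(mat)
  rowBytes <- ((w + 3) %/% 4) * 4
  dataSize <- rowBytes * h
  off <- 14L + 40L + 256L * 4L
  u <- function(x, n) writeBin(as.integer(x), con, size = n,
                               endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u(off + dataSize, 4); u(0, 4); u(off, 4)
  u(40, 4); u(w, 4); u(h, 4); u(1, 2); u(8, 2); u(0, 4); u(dataSize, 4)
  u(2835, 4); u(2835, 4); u(256, 4); u(0, 4)
  for (i in 0:255) writeBin(as.raw(c(i, i, i, 0)), con)   # B G R reserved
  pad <- raw(rowBytes - w)
  for (r in rev(seq_len(h))) {                            # bottom-up rows
    writeBin(as.raw(round(mat[r, ])), con)
    writeBin(pad, con)
  }
  invisible(path)
}

# uncompressed 24-bit BGR BMP
writeTestBMP24 <- function(rgb, path) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  rowBytes <- ((3 * w + 3) %/% 4) * 4
  dataSize <- rowBytes * h
  off <- 14L + 40L
  con <- file(path, "wb")
  on.exit(close(con))
  u <- function(x, n) writeBin(as.integer(x), con, size = n,
                               endian = "little")
  writeBin(charToRaw("BM"), con)
  u(off + dataSize, 4); u(0, 4); u(off, 4)
  u(40, 4); u(w, 4); u(h, 4); u(1, 2); u(24, 2); u(0, 4); u(dataSize, 4)
  u(2835, 4); u(2835, 4); u(0, 4); u(0, 4)
  pad <- raw(rowBytes - 3 * w)
  for (r in rev(seq_len(h))) {
    bgr <- rbind(rgb[r, , 3], rgb[r, , 2], rgb[r, , 1])
    writeBin(as.raw(round(as.vector(bgr))), con)
    writeBin(pad, con)
  }
  invisible(path)
}

# minimal explicit-VR little-endian DICOM with 16-bit unsigned pixel data
writeTestDICOM <- function(mat, path, instance = 1, slope = 1,
                           intercept = 0, spacing = 0.2) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  tagShort <- function(group, elem, vr, bytes) {
    writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
    writeBin(charToRaw(vr), con)
    writeBin(as.integer(length(bytes)), con, size = 2, endian = "little")
    writeBin(bytes, con)
  }
  tagLong <- function(group, elem, vr, bytes) {
    writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
    writeBin(charToRaw(vr), con)
    writeBin(as.integer(0), con, size = 2, endian = "little")
    writeBin(as.integer(length(bytes)), con, size = 4, endian = "little")
    writeBin(bytes, con)
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
  str <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 2) b <- c(b, charToRaw(" "))
    b
  }
  tagShort(0x0020, 0x0013, "IS", str(as.character(instance)))
  tagShort(0x0028, 0x0010, "US", us(nrow(mat)))
  tagShort(0x0028, 0x0011, "US", us(ncol(mat)))
  tagShort(0x0028, 0x0030, "DS",
           str(paste(spacing, spacing, sep = "\\")))
  tagShort(0x0028, 0x0100, "US", us(16))
  tagShort(0x0028, 0x0103, "US", us(0))
  tagShort(0x0028, 0x1052, "DS", str(as.character(intercept)))
  tagShort(0x0028, 0x1053, "DS", str(as.character(slope)))
  px <- writeBin(as.integer(round(t(mat))), raw(), size = 2,
                 endian = "little")
  tagLong(0x7fe0, 0x0010, "OW", px)
  invisible(path)
}

expectReportsEqual <- function(a, b) {
  testthat::expect_identical(a@offCounts@counts, b@offCounts@counts)
  testthat::expect_identical(a@onCounts@counts, b@onCounts@counts)
  testthat::expect_identical(a@perSliceDiff, b@perSliceDiff)
  testthat::expect_identical(a@totalOff, b@totalOff)
  testthat::expect_identical(a@totalOn, b@totalOn)
  testthat::expect_identical(a@reductionRatioPct, b@reductionRatioPct)
}
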