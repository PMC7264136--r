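#' @include AllClasses.R
NULL

## Minimal readers for the two slice formats without an installed R package:
## uncompressed BMP (8-bit palette/gray and 24-bit BGR) and uncompressed
## little-endian single-frame DICOM. Both cover the subset produced by CBCT
## console exports; compressed transfer syntaxes are out of scope.

readU <- function(raw, off, n) {
  # little-endian unsigned integer of n bytes starting at 1-based offset
  sum(as.numeric(raw[off + seq_len(n) - 1L]) * 256^(seq_len(n) - 1L))
}

#' Read an uncompressed BMP image
#'
#' Supports 8-bit (palette interpreted through its gray levels) and 24-bit
#' BGR Windows bitmaps with BITMAPINFOHEADER, the variant produced by
#' "save as BMP" exports. Returns intensities on the 0-255 scale, converting
#' color input with ITU-R BT.601 luma weights.
#'
#' @param path BMP file path.
#' @return numeric intensity matrix.
#' @export
readBMP <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file")
  dataOff <- readU(raw, 11L, 4L)
  hdrSize <- readU(raw, 15L, 4L)
  if (hdrSize < 40) stop("unsupported BMP header")
  width <- readU(raw, 19L, 4L)
  heightRaw <- readU(raw, 23L, 4L)
  topDown <- heightRaw > 2^31
  height <- if (topDown) 2^32 - heightRaw else heightRaw
  bpp <- readU(raw, 29L, 2L)
  compression <- readU(raw, 31L, 4L)
  if (compression != 0) stop("compressed BMP is not supported")
  if (!bpp %in% c(8, 24)) stop("only 8-bit and 24-bit BMP are supported")
  if (bpp == 8) {
    nPal <- readU(raw, 47L, 4L)
    if (nPal == 0) nPal <- 256
    palOff <- 14L + hdrSize
    pal <- matrix(as.numeric(raw[palOff + seq_len(nPal * 4L)]),
                  ncol = 4L, byrow = TRUE)           # B, G, R, reserved
    gray <- 0.299 * pal[, 3L] + 0.587 * pal[, 2L] + 0.114 * pal[, 1L]
    rowBytes <- ((width + 3) %/% 4) * 4
    out <- matrix(0, height, width)
    for (r in seq_len(height)) {
      start <- dataOff + (r - 1L) * rowBytes
      idx <- as.integer(raw[start + seq_len(width)]) + 1L
      out[r, ] <- gray[idx]
    }
  } else {
    rowBytes <- ((3 * width + 3) %/% 4) * 4
    out <- matrix(0, height, width)
    for (r in seq_len(height)) {
      start <- dataOff + (r - 1L) * rowBytes
      px <- matrix(as.numeric(raw[start + seq_len(3L * width)]),
                   nrow = 3L)                         # B, G, R columns
      out[r, ] <- 0.299 * px[3L, ] + 0.587 * px[2L, ] + 0.114 * px[1L, ]
    }
  }
  if (!topDown) out <- out[rev(seq_len(height)), , drop = FALSE]
  out
}

dicomVRs32 <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a single-frame uncompressed DICOM slice
#'
#' Minimal parser for explicit- and implicit-VR little-endian transfer
#' syntaxes with uncompressed pixel data, extracting rows, columns, bit
#' depth, pixel representation, rescale slope/intercept, instance number and
#' pixel spacing. Stored values are mapped through slope/intercept; the
#' caller performs the per-stack min-max rescale to [0, 255]. Sequences with
#' undefined length and compressed transfer syntaxes are not supported.
#'
#' @param path DICOM file path.
#' @return list with `pixels` (numeric matrix of rescaled values),
#'   `instance` (instance number) and `spacing` (row pixel spacing in mm,
#'   `NA` if absent).
#' @export
readDICOMSlice <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  if (length(raw) >= pos + 5L) {
    vrGuess <- rawToChar(raw[pos + 4:5])
    explicit <- grepl("^[A-Z]{2}$", vrGuess)
  }
  fields <- list(rows = NA, cols = NA, bits = 16, signed = 0,
                 slope = 1, intercept = 0, instance = 0, spacing = NA_real_,
                 pixdata = NULL)
  while (pos + 7L <= length(raw)) {
    group <- readU(raw, pos, 2L); elem <- readU(raw, pos + 2L, 2L)
    pos <- pos + 4L
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(raw[pos + 0:1])
      if (vr %in% dicomVRs32) {
        len <- readU(raw, pos + 4L, 4L); pos <- pos + 8L
      } else {
        len <- readU(raw, pos + 2L, 2L); pos <- pos + 4L
      }
    } else {
      vr <- ""
      len <- readU(raw, pos, 4L); pos <- pos + 4L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM elements are not supported")
    val <- raw[pos + seq_len(len) - 1L]
    tag <- sprintf("%04x,%04x", group, elem)
    txt <- function() trimws(rawToChar(val))
    if (tag == "0028,0010") fields$rows <- readU(val, 1L, 2L)
    else if (tag == "0028,0011") fields$cols <- readU(val, 1L, 2L)
    else if (tag == "0028,0100") fields$bits <- readU(val, 1L, 2L)
    else if (tag == "0028,0103") fields$signed <- readU(val, 1L, 2L)
    else if (tag == "0028,1052") fields$intercept <- as.numeric(txt())
    else if (tag == "0028,1053") fields$slope <- as.numeric(txt())
    else if (tag == "0020,0013") fields$instance <- as.numeric(txt())
    else if (tag == "0028,0030")
      fields$spacing <- as.numeric(strsplit(txt(), "\\\\")[[1L]][1L])
    else if (tag == "7fe0,0010") fields$pixdata <- val
    pos <- pos + len
  }
  if (is.na(fields$rows) || is.na(fields$cols) || is.null(fields$pixdata))
    stop("missing rows/columns/pixel data")
  nPix <- fields$rows * fields$cols
  if (fields$bits == 8) {
    v <- as.numeric(fields$pixdata[seq_len(nPix)])
  } else if (fields$bits == 16) {
    if (length(fields$pixdata) < 2L * nPix) stop("truncated pixel data")
    v <- readBin(fields$pixdata, "integer", n = nPix, size = 2L,
                 signed = fields$signed == 1, endian = "little")
    if (fields$signed == 0) v <- v + ifelse(v < 0, 65536, 0)
  } else stop("unsupported bit depth: ", fields$bits)
  v <- fields$slope * v + fields$intercept
  # DICOM pixel data is row-major (rows of the image in sequence)
  pixels <- matrix(v, nrow = fields$rows, ncol = fields$cols, byrow = TRUE)
  list(pixels = pixels, instance = fields$instance, spacing = fields$spacing)
}
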