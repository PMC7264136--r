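#' @include AllClasses.R
NULL

# Natural sort: split file names into digit / non-digit tokens so that
# slice2 < slice10, matching how exported stacks are usually named.
naturalOrder <- function(x) {
  toks <- strsplit(x, "(?<=\\D)(?=\\d)|(?<=\\d)(?=\\D)", perl = TRUE)
  width <- max(vapply(toks, length, integer(1)))
  keys <- vapply(seq_len(width), function(i) {
    t <- vapply(toks, function(tt) if (i <= length(tt)) tt[i] else "",
                character(1))
    num <- suppressWarnings(as.numeric(t))
    if (all(!is.na(num) | t == ""))
      sprintf("%020.4f", ifelse(is.na(num), -1, num))
    else t
  }, character(length(x)))
  if (is.null(dim(keys))) keys <- matrix(keys, nrow = length(x))
  do.call(order, c(lapply(seq_len(ncol(keys)), function(j) keys[, j]),
                   list(x)))
}

# ITU-R BT.601 luma weights, the conventional grayscale conversion for
# multi-channel 8-bit imagery. Already-gray input passes through unchanged.
lumaGray <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  if (dim(a)[3] == 1L) return(a[, , 1L])
  0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
}

readBitmapSlice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           bmp = readBMP(path),
           stop("unsupported bitmap extension: ", ext)),
    error = function(e)
      stop("format error reading '", basename(path), "': ",
           conditionMessage(e), call. = FALSE))
  if (ext == "bmp") return(a)        # already on the 0-255 scale
  lumaGray(a) * 255                  # readPNG/readTIFF are scaled to [0, 1]
}

#' Read an axial image stack from a slice directory or DICOM series
#'
#' Bitmap-family directories (BMP/PNG/TIFF) are read in natural-sort file
#' order; DICOM series are ordered by instance number. Multi-channel input
#' is converted to grayscale with ITU-R BT.601 luma weights, and source bit
#' depths other than 8 are rescaled so the full source range maps to
#' [0, 255]. DICOM stored values pass through the rescale slope/intercept
#' and are then min-max scaled to [0, 255] per stack (not per slice), so
#' inter-slice contrast is preserved.
#'
#' @param path directory containing the slice files.
#' @param formatHint `"auto"` (default; decided from the file extensions),
#'   `"bitmap"` or `"dicom"`.
#' @param marState,prosthesis,voxelMM,kvp acquisition label attached to the
#'   returned stack.
#' @return a validated [ImageStack-class].
#' @seealso [trimBlankSlices()], [pairStacks()]
#' @export
readStack <- function(path, formatHint = c("auto", "bitmap", "dicom"),
                      marState = "off", prosthesis = "synthetic",
                      voxelMM = NA_real_, kvp = NA_real_) {
  formatHint <- match.arg(formatHint)
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  exts <- tolower(tools::file_ext(files))
  keep <- exts %in% c("png", "tif", "tiff", "bmp", "dcm", "dicom")
  files <- files[keep]; exts <- exts[keep]
  if (length(files) == 0L) stop("no input: directory contains no image files")
  isDicom <- if (formatHint == "auto") any(exts %in% c("dcm", "dicom"))
             else formatHint == "dicom"
  spacing <- NA_real_
  if (isDicom) {
    raw <- lapply(files, function(f)
      tryCatch(readDICOMSlice(f), error = function(e)
        stop("format error reading '", basename(f), "': ",
             conditionMessage(e), call. = FALSE)))
    ord <- order(vapply(raw, function(s) s$instance, numeric(1)))
    raw <- raw[ord]
    mats <- lapply(raw, `[[`, "pixels")
    spacing <- raw[[1L]]$spacing
    dims <- unique(lapply(mats, dim))
    if (length(dims) != 1L)
      stop("inconsistent stack: slices have mixed dimensions")
    lo <- min(vapply(mats, min, numeric(1)))
    hi <- max(vapply(mats, max, numeric(1)))
    mats <- lapply(mats, function(m)
      if (hi > lo) (m - lo) / (hi - lo) * 255 else m * 0)
  } else {
    files <- files[naturalOrder(basename(files))]
    mats <- lapply(files, readBitmapSlice)
    dims <- unique(lapply(mats, dim))
    if (length(dims) != 1L)
      stop("inconsistent stack: slices have mixed dimensions")
  }
  st <- imageStack(mats, marState = marState, prosthesis = prosthesis,
                   voxelMM = voxelMM, kvp = kvp, pixelSpacing = spacing)
  validObject(st)
  st
}

#' Trim blank leading and trailing slices
#'
#' Axial slices above and below the object carry no signal and are excluded
#' before counting. A slice is blank when the fraction of its pixels above
#' `blankThreshold` is below `minFraction`; only the maximal leading and
#' trailing runs of blank slices are removed (interior blank slices are
#' retained), and the remaining slices are re-based to index 0.
#' Idempotent: trimming a trimmed stack changes nothing.
#'
#' @param stack an [ImageStack-class].
#' @param blankThreshold intensity on the 0-255 scale (default 10).
#' @param minFraction proportion in (0, 1) (default 0.005).
#' @return the trimmed [ImageStack-class].
#' @export
trimBlankSlices <- function(stack, blankThreshold = 10, minFraction = 0.005) {
  stopifnot(is(stack, "ImageStack"))
  if (blankThreshold < 0 || blankThreshold > 255)
    stop("blankThreshold must lie in [0, 255]")
  if (!(minFraction > 0 && minFraction < 1))
    stop("minFraction must lie in (0, 1)")
  n <- nSlices(stack)
  frac <- vapply(seq_len(n), function(i)
    mean(stack@slices[, , i] > blankThreshold), numeric(1))
  keep <- frac >= minFraction
  if (!any(keep))
    stop("empty after trim: all slices are blank")
  first <- which(keep)[1L]; last <- which(keep)[sum(keep)]
  out <- stack
  out@slices <- stack@slices[, , first:last, drop = FALSE]
  out
}

#' Pair a MAR-off and a MAR-on stack
#'
#' Validates the pairing invariants (equal slice counts and dimensions,
#' identical prosthesis/voxel/kVp labels, complementary MAR states); slices
#' are paired by equal post-trim index.
#'
#' @param off,on trimmed [ImageStack-class] objects.
#' @return a [StackPair-class].
#' @export
pairStacks <- function(off, on) {
  stopifnot(is(off, "ImageStack"), is(on, "ImageStack"))
  p <- new("StackPair", offStack = off, onStack = on)
  validObject(p)
  p
}

fmtNum <- function(x) {
  # %.17g round-trips doubles exactly through text
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

labelString <- function(s)
  paste(s@marState, s@prosthesis, fmtNum(s@voxelMM), fmtNum(s@kvp),
        sep = "|")

parseLabel <- function(txt) {
  parts <- strsplit(txt, "|", fixed = TRUE)[[1L]]
  num <- function(s) if (identical(s, "NA")) NA_real_ else as.numeric(s)
  list(marState = parts[1L], prosthesis = parts[2L],
       voxelMM = num(parts[3L]), kvp = num(parts[4L]))
}

reportFrame <- function(report) {
  n <- length(report@perSliceDiff)
  data.frame(
    record = c(rep("slice", n), "summary"),
    slice = c(seq_len(n) - 1L, NA_integer_),
    off_count = c(report@offCounts@counts, report@totalOff),
    on_count = c(report@onCounts@counts, report@totalOn),
    diff = c(report@perSliceDiff, report@totalOff - report@totalOn),
    reduction_ratio_pct = c(rep(NA_real_, n), report@reductionRatioPct),
    mean_diff = c(rep(NA_real_, n), report@meanDiff),
    sd_diff = c(rep(NA_real_, n), report@sdDiff),
    off_label = c(rep(NA_character_, n), labelString(report@offCounts)),
    on_label = c(rep(NA_character_, n), labelString(report@onCounts)),
    stringsAsFactors = FALSE)
}

#' Write a reduction report to CSV or JSON
#'
#' The CSV has one row per slice (index, off count, on count, difference)
#' plus one summary row carrying the totals, the reduction ratio and the
#' mean/SD of the per-slice differences; floating-point fields are written
#' with 17 significant digits so that [readReport()] reproduces all counts
#' and the ratio exactly. The JSON file mirrors the full report.
#'
#' @param report a [ReductionReport-class].
#' @param path output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("auto", "csv", "json")) {
  stopifnot(is(report, "ReductionReport"))
  validObject(report)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (format == "csv") {
    df <- reportFrame(report)
    for (col in c("reduction_ratio_pct", "mean_diff", "sd_diff"))
      df[[col]] <- fmtNum(df[[col]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    obj <- list(
      off_label = stackLabel(report@offCounts),
      on_label = stackLabel(report@onCounts),
      off_counts = report@offCounts@counts,
      on_counts = report@onCounts@counts,
      per_slice_diff = report@perSliceDiff,
      total_off = report@totalOff, total_on = report@totalOn,
      reduction_ratio_pct = report@reductionRatioPct,
      mean_diff = report@meanDiff, sd_diff = report@sdDiff)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

countSeriesFromLabel <- function(counts, lab) {
  numOrNA <- function(x)
    if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
  new("EdgeCountSeries", counts = as.integer(counts),
      marState = lab$marState, prosthesis = lab$prosthesis,
      voxelMM = numOrNA(lab$voxelMM), kvp = numOrNA(lab$kvp))
}

#' Read back a reduction report
#'
#' Inverse of [writeReport()]; the read/write round trip is the identity on
#' all counts and on the reduction ratio.
#'
#' @param path CSV or JSON file written by [writeReport()].
#' @return a [ReductionReport-class].
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    offC <- countSeriesFromLabel(obj$off_counts, obj$off_label)
    onC <- countSeriesFromLabel(obj$on_counts, obj$on_label)
    return(new("ReductionReport", offCounts = offC, onCounts = onC,
               perSliceDiff = as.integer(obj$per_slice_diff),
               totalOff = as.integer(obj$total_off),
               totalOn = as.integer(obj$total_on),
               reductionRatioPct = as.numeric(obj$reduction_ratio_pct),
               meanDiff = as.numeric(obj$mean_diff),
               sdDiff = as.numeric(obj$sd_diff)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sl <- df[df$record == "slice", ]
  sm <- df[df$record == "summary", ]
  offC <- countSeriesFromLabel(sl$off_count, parseLabel(sm$off_label))
  onC <- countSeriesFromLabel(sl$on_count, parseLabel(sm$on_label))
  new("ReductionReport", offCounts = offC, onCounts = onC,
      perSliceDiff = as.integer(sl$diff),
      totalOff = as.integer(sm$off_count),
      totalOn = as.integer(sm$on_count),
      reductionRatioPct = as.numeric(sm$reduction_ratio_pct),
      meanDiff = as.numeric(sm$mean_diff),
      sdDiff = as.numeric(sm$sd_diff))
}

#' Write an edge map as a binary PNG
#'
#' Edge pixels are written white on black for visual inspection, or overlaid
#' on a baseline slice when `baseline` is supplied (edges at full white over
#' the dimmed slice).
#'
#' @param map an [EdgeMap-class].
#' @param path output PNG path.
#' @param baseline optional numeric matrix (the source slice, 0-255 scale).
#' @return `path`, invisibly.
#' @export
writeEdgeMap <- function(map, path, baseline = NULL) {
  stopifnot(is(map, "EdgeMap"))
  px <- map@pixels * 1
  if (!is.null(baseline)) {
    if (!identical(dim(baseline), dim(map@pixels)))
      stop("baseline dimensions must match the edge map")
    px <- pmin(0.5 * baseline / 255 + px, 1)
  }
  png::writePNG(px, path)
  invisible(path)
}

#' Write an image stack as a PNG slice directory
#'
#' Emits `slice_000.png`, `slice_001.png`, ... in slice order; a directory
#' written this way reads back identically with [readStack()].
#'
#' @param stack an [ImageStack-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeStack <- function(stack, dir) {
  stopifnot(is(stack, "ImageStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nSlices(stack))) {
    png::writePNG(stack@slices[, , i] / 255,
                  file.path(dir, sprintf("slice_%03d.png", i - 1L)))
  }
  invisible(dir)
}
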