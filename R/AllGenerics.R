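#' @include AllClasses.R
NULL

#' Number of slices in a stack
#' @param x an [ImageStack-class], [StackPair-class] or [SimulatedPair-class].
#' @return integer slice count.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' Slice dimensions
#' @param x an [ImageStack-class] or [StackPair-class].
#' @return integer vector `(rows, cols)`.
#' @export
setGeneric("sliceDims", function(x) standardGeneric("sliceDims"))

#' Extract one slice as a matrix
#' @param x an [ImageStack-class].
#' @param i slice index, 0-based to match the external slice numbering.
#' @return numeric matrix of intensities in [0, 255].
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' Acquisition label of an object
#' @param x an [ImageStack-class] or [EdgeCountSeries-class].
#' @return named list with `marState`, `prosthesis`, `voxelMM`, `kvp`.
#' @export
setGeneric("stackLabel", function(x) standardGeneric("stackLabel"))

#' Per-slice edge counts
#' @param x an [EdgeCountSeries-class] or [ReductionReport-class].
#' @param ... passed to methods.
#' @return integer vector of counts (for a report, a two-column matrix with
#'   `off` and `on` columns).
#' @export
setGeneric("edgeCounts", function(x, ...) standardGeneric("edgeCounts"))

#' @rdname nSlices
#' @export
setMethod("nSlices", "ImageStack", function(x) dim(x@slices)[3])

#' @rdname nSlices
#' @export
setMethod("nSlices", "StackPair", function(x) dim(x@offStack@slices)[3])

#' @rdname nSlices
#' @export
setMethod("nSlices", "SimulatedPair", function(x) nSlices(x@pair))

#' @rdname sliceDims
#' @export
setMethod("sliceDims", "ImageStack", function(x) dim(x@slices)[1:2])

#' @rdname sliceDims
#' @export
setMethod("sliceDims", "StackPair", function(x) sliceDims(x@offStack))

#' @rdname getSlice
#' @export
setMethod("getSlice", "ImageStack", function(x, i) {
  i <- as.integer(i)
  if (i < 0L || i >= nSlices(x))
    stop("slice index out of range [0, ", nSlices(x) - 1L, "]")
  x@slices[, , i + 1L]
})

#' @rdname stackLabel
#' @export
setMethod("stackLabel", "ImageStack", function(x)
  list(marState = x@marState, prosthesis = x@prosthesis,
       voxelMM = x@voxelMM, kvp = x@kvp))

#' @rdname stackLabel
#' @export
setMethod("stackLabel", "EdgeCountSeries", function(x)
  list(marState = x@marState, prosthesis = x@prosthesis,
       voxelMM = x@voxelMM, kvp = x@kvp))

#' @rdname edgeCounts
#' @export
setMethod("edgeCounts", "EdgeCountSeries", function(x, ...) x@counts)

#' @rdname edgeCounts
#' @export
setMethod("edgeCounts", "ReductionReport", function(x, ...)
  cbind(off = x@offCounts@counts, on = x@onCounts@counts))

#' Reduction ratio stored in a report
#' @param report a [ReductionReport-class].
#' @return the edge reduction ratio in percent.
#' @export
reductionRatioPct <- function(report) {
  stopifnot(is(report, "ReductionReport"))
  report@reductionRatioPct
}

setMethod("show", "EdgeParams", function(object) {
  thr <- if (object@thresholdMode == "fixed" ||
             !is.na(object@highThreshold))
    sprintf("low %.4g, high %.4g", object@lowThreshold, object@highThreshold)
  else
    sprintf("auto (q%.2f of positive magnitudes, ratio %.2f)",
            object@highPercentile, object@lowHighRatio)
  cat("EdgeParams: denoise", object@denoiseMethod,
      "| sigma", format(object@gaussianSigma),
      "| thresholds", thr, "\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@slices)
  cat(sprintf("ImageStack: %d slice(s) of %dx%d, MAR %s, %s",
              d[3], d[1], d[2], object@marState, object@prosthesis))
  if (!is.na(object@voxelMM)) cat(sprintf(", %.2g mm voxel", object@voxelMM))
  if (!is.na(object@kvp)) cat(sprintf(", %g kVp", object@kvp))
  cat(sprintf("; intensities [%.4g, %.4g]\n",
              min(object@slices), max(object@slices)))
})

setMethod("show", "StackPair", function(object) {
  cat("StackPair of", nSlices(object), "paired slices (",
      paste(sliceDims(object), collapse = "x"), ")\n")
})

setMethod("show", "EdgeMap", function(object) {
  cat(sprintf("EdgeMap %dx%d, %d edge pixel(s)\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels)))
})

setMethod("show", "EdgeCountSeries", function(object) {
  cat(sprintf("EdgeCountSeries (MAR %s, %s): %d slice(s), total %d\n",
              object@marState, object@prosthesis, length(object@counts),
              sum(object@counts)))
})

setMethod("show", "ReductionReport", function(object) {
  cat(sprintf(paste0("ReductionReport: %d slices | edges off %d, on %d | ",
                     "reduction %.2f%% | per-slice diff %.2f +/- %.2f\n"),
              length(object@perSliceDiff), object@totalOff, object@totalOn,
              object@reductionRatioPct, object@meanDiff, object@sdDiff))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %dx%dx%d, background %g, arch %g, ",
                     "insert %g (r = %g px)\n"),
              object@sliceDims[1], object@sliceDims[2], object@nSlices,
              object@backgroundIntensity, object@archIntensity,
              object@insertIntensity, object@insertRadius))
})

setMethod("show", "SimulatedPair", function(object) {
  cat(sprintf(paste0("SimulatedPair: %d off-streaks vs %d on-streaks per ",
                     "slice, true reduction %.1f%% (seed %d)\n"),
              object@kOff, object@kOn, object@trueRatioPct, object@seed))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n  ")
  show(object@edgeParams)
  cat(sprintf("  blankThreshold %g, minFraction %g, connectivity %d, alpha %g\n",
              object@blankThreshold, object@minFraction,
              object@connectivity, object@alpha))
})
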