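#' @import methods
NULL

## Central S4 containers. Intensities are kept as doubles on the 8-bit
## [0, 255] scale throughout; slices are matrices in row-major screen
## convention (origin top-left, 0-based slice indices in the external
## interface, 1-based matrix indexing internally as usual in R).

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Parameters of the modified Canny edge detector
#'
#' Bundles every tunable of the edge-detection stage: the up-front noise
#' removal method, the Gaussian smoothing scale, and the hysteresis threshold
#' policy. In `"auto"` mode the high threshold is the `highPercentile`
#' quantile (linear interpolation between order statistics) of the positive
#' gradient magnitudes of the thinned gradient image, and the low threshold is
#' `lowHighRatio` times the high one; in `"fixed"` mode `lowThreshold` and
#' `highThreshold` are used verbatim.
#'
#' @slot denoiseMethod `"median3"` (3x3 median filter, reflected borders) or
#'   `"none"`.
#' @slot gaussianSigma positive Gaussian smoothing sigma in pixels.
#' @slot lowHighRatio low/high threshold ratio in (0, 1), used in auto mode.
#' @slot highPercentile quantile level in (0, 1) defining the high threshold
#'   in auto mode.
#' @slot thresholdMode `"auto"` or `"fixed"`.
#' @slot lowThreshold,highThreshold gradient-magnitude thresholds; `NA` unless
#'   fixed mode is selected or the values have been materialized by a run.
#' @seealso [edgeParams()], [detectEdges()]
#' @exportClass EdgeParams
setClass("EdgeParams",
  representation(
    denoiseMethod  = "character",
    gaussianSigma  = "numeric",
    lowHighRatio   = "numeric",
    highPercentile = "numeric",
    thresholdMode  = "character",
    lowThreshold   = "numeric",
    highThreshold  = "numeric"
  )
)

setValidity("EdgeParams", function(object) {
  msg <- character()
  if (!object@denoiseMethod %in% c("median3", "none"))
    msg <- c(msg, "denoiseMethod must be 'median3' or 'none'")
  if (length(object@gaussianSigma) != 1L || !is.finite(object@gaussianSigma) ||
      object@gaussianSigma <= 0)
    msg <- c(msg, "gaussianSigma must be a single positive number")
  if (!(object@lowHighRatio > 0 && object@lowHighRatio < 1))
    msg <- c(msg, "lowHighRatio must lie in (0, 1)")
  if (!(object@highPercentile > 0 && object@highPercentile < 1))
    msg <- c(msg, "highPercentile must lie in (0, 1)")
  if (!object@thresholdMode %in% c("auto", "fixed"))
    msg <- c(msg, "thresholdMode must be 'auto' or 'fixed'")
  if (object@thresholdMode == "fixed") {
    if (is.na(object@lowThreshold) || is.na(object@highThreshold))
      msg <- c(msg, "fixed mode requires lowThreshold and highThreshold")
    else if (!(object@lowThreshold < object@highThreshold))
      msg <- c(msg, "lowThreshold must be smaller than highThreshold")
  }
  if (length(msg)) msg else TRUE
})

#' Construct edge-detection parameters
#'
#' Defaults give a conventional automatic Canny parameterization with an
#' additional 3x3 median pre-filter that removes impulse noise before the
#' Gaussian stage (isolated hot pixels otherwise survive as spurious
#' one-pixel edge components and corrupt edge counts).
#'
#' @param denoiseMethod `"median3"` or `"none"`.
#' @param gaussianSigma Gaussian sigma in pixels (default 1.4).
#' @param lowHighRatio ratio of low to high hysteresis threshold (default 0.4).
#' @param highPercentile quantile of positive thinned gradient magnitudes
#'   defining the high threshold in auto mode (default 0.7).
#' @param thresholdMode `"auto"` or `"fixed"`.
#' @param lowThreshold,highThreshold absolute thresholds for fixed mode.
#' @return An [EdgeParams-class] object.
#' @examples
#' edgeParams()
#' edgeParams(thresholdMode = "fixed", lowThreshold = 20, highThreshold = 60)
#' @export
edgeParams <- function(denoiseMethod = "median3", gaussianSigma = 1.4,
                       lowHighRatio = 0.4, highPercentile = 0.7,
                       thresholdMode = c("auto", "fixed"),
                       lowThreshold = NA_real_, highThreshold = NA_real_) {
  new("EdgeParams",
      denoiseMethod = match.arg(denoiseMethod, c("median3", "none")),
      gaussianSigma = as.numeric(gaussianSigma),
      lowHighRatio = as.numeric(lowHighRatio),
      highPercentile = as.numeric(highPercentile),
      thresholdMode = match.arg(thresholdMode),
      lowThreshold = as.numeric(lowThreshold),
      highThreshold = as.numeric(highThreshold))
}

#' Ordered stack of axial grayscale slices from one acquisition
#'
#' The unit over which edge counts are computed. Slices are stored as a
#' rows x cols x slices array of intensities on the 8-bit [0, 255] scale;
#' the label records the acquisition condition (MAR state, prosthesis type,
#' voxel size, tube voltage).
#'
#' @slot slices numeric array, rows x cols x nSlices, values in [0, 255].
#' @slot marState `"off"` or `"on"`.
#' @slot prosthesis one of `"amalgam"`, `"gold"`, `"pfm"`, `"zirconia"`,
#'   `"synthetic"`.
#' @slot voxelMM voxel edge length in mm (`NA` if unknown).
#' @slot kvp peak tube voltage in kVp (`NA` if unknown).
#' @slot pixelSpacing physical pixel size in mm (`NA` if unknown).
#' @seealso [readStack()], [trimBlankSlices()], [countStack()]
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    slices       = "array",
    marState     = "character",
    prosthesis   = "character",
    voxelMM      = "numeric",
    kvp          = "numeric",
    pixelSpacing = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@slices)
  msg <- character()
  if (length(d) != 3L)
    return("slices must be a rows x cols x nSlices array")
  if (d[3] < 1L) msg <- c(msg, "stack must contain at least one slice")
  if (d[1] < 8L || d[2] < 8L)
    msg <- c(msg, "slice dimensions must both be >= 8")
  rng <- range(object@slices)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    msg <- c(msg, "intensities must be finite and within [0, 255]")
  if (!object@marState %in% c("off", "on"))
    msg <- c(msg, "marState must be 'off' or 'on'")
  if (!object@prosthesis %in%
        c("amalgam", "gold", "pfm", "zirconia", "synthetic"))
    msg <- c(msg, "unknown prosthesis label")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param slices a rows x cols x nSlices numeric array, a single matrix
#'   (promoted to one slice), or a list of equally sized matrices; values on
#'   the [0, 255] scale.
#' @param marState `"off"` or `"on"`.
#' @param prosthesis prosthesis label; `"synthetic"` for simulated data.
#' @param voxelMM,kvp,pixelSpacing acquisition metadata (`NA` if unknown).
#' @return An [ImageStack-class].
#' @examples
#' st <- imageStack(matrix(0, 16, 16))
#' nSlices(st)
#' @export
imageStack <- function(slices, marState = "off", prosthesis = "synthetic",
                       voxelMM = NA_real_, kvp = NA_real_,
                       pixelSpacing = NA_real_) {
  if (is.list(slices)) {
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L)
      stop("inconsistent stack: slices have mixed dimensions")
    slices <- array(unlist(slices, use.names = FALSE),
                    dim = c(dims[[1]], length(slices)))
  } else if (is.matrix(slices)) {
    slices <- array(slices, dim = c(dim(slices), 1L))
  }
  new("ImageStack", slices = slices, marState = marState,
      prosthesis = prosthesis, voxelMM = as.numeric(voxelMM),
      kvp = as.numeric(kvp), pixelSpacing = as.numeric(pixelSpacing))
}

#' Paired MAR-off / MAR-on acquisitions of the same object
#'
#' Validity requires equal slice counts and dimensions and identical
#' prosthesis / voxel / kVp labels; only the MAR state differs. Slices are
#' paired by equal post-trim index.
#'
#' @slot offStack [ImageStack-class] acquired with MAR disabled.
#' @slot onStack [ImageStack-class] acquired with MAR enabled.
#' @seealso [pairStacks()], [analyzePair()]
#' @exportClass StackPair
setClass("StackPair",
  representation(offStack = "ImageStack", onStack = "ImageStack"))

setValidity("StackPair", function(object) {
  off <- object@offStack; on <- object@onStack
  msg <- character()
  if (off@marState != "off" || on@marState != "on")
    msg <- c(msg, "offStack must have marState 'off' and onStack 'on'")
  doff <- dim(off@slices); don <- dim(on@slices)
  if (doff[3] != don[3])
    msg <- c(msg, sprintf("pairing error: %d vs %d slices", doff[3], don[3]))
  if (any(doff[1:2] != don[1:2]))
    msg <- c(msg, "paired stacks must have equal slice dimensions")
  if (off@prosthesis != on@prosthesis ||
      !identical(off@voxelMM, on@voxelMM) || !identical(off@kvp, on@kvp))
    msg <- c(msg, "label error: prosthesis/voxel/kvp labels differ")
  if (length(msg)) msg else TRUE
})

#' Binary edge image of one slice
#'
#' Output of the Canny stage: a logical matrix with the source slice's
#' dimensions, together with the parameters actually used (auto thresholds
#' materialized).
#'
#' @slot pixels logical matrix; `TRUE` marks edge pixels.
#' @slot paramsUsed [EdgeParams-class] with resolved thresholds.
#' @seealso [detectEdges()], [countEdges()], [writeEdgeMap()]
#' @exportClass EdgeMap
setClass("EdgeMap",
  representation(pixels = "matrix", paramsUsed = "EdgeParams"))

setValidity("EdgeMap", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (anyNA(object@pixels)) return("pixels must not contain NA")
  TRUE
})

#' Per-slice edge counts of one stack
#'
#' @slot counts non-negative integer vector, one entry per slice, in slice
#'   order.
#' @slot marState,prosthesis,voxelMM,kvp acquisition label, copied from the
#'   source stack.
#' @seealso [countStack()], [sliceDifferences()]
#' @exportClass EdgeCountSeries
setClass("EdgeCountSeries",
  representation(counts = "integer", marState = "character",
                 prosthesis = "character", voxelMM = "numeric",
                 kvp = "numeric"))

setValidity("EdgeCountSeries", function(object) {
  if (length(object@counts) < 1L) return("counts must be non-empty")
  if (anyNA(object@counts) || any(object@counts < 0L))
    return("counts must be non-negative integers")
  TRUE
})

#' Paired edge-count analysis of one MAR-off/MAR-on pair
#'
#' Holds both per-slice count series, the per-slice differences
#' (off minus on), the stack totals, the edge reduction ratio computed on the
#' totals, and the mean and sample standard deviation (n-1 denominator) of
#' the per-slice differences.
#'
#' @slot offCounts,onCounts [EdgeCountSeries-class] for each MAR state.
#' @slot perSliceDiff integer vector, off minus on per slice.
#' @slot totalOff,totalOn stack totals.
#' @slot reductionRatioPct `100 * (totalOff - totalOn) / totalOff`.
#' @slot meanDiff,sdDiff moments of the per-slice differences.
#' @seealso [analyzePair()], [writeReport()], [perSliceRatios()]
#' @exportClass ReductionReport
setClass("ReductionReport",
  representation(offCounts = "EdgeCountSeries", onCounts = "EdgeCountSeries",
                 perSliceDiff = "integer", totalOff = "integer",
                 totalOn = "integer", reductionRatioPct = "numeric",
                 meanDiff = "numeric", sdDiff = "numeric"))

setValidity("ReductionReport", function(object) {
  n <- length(object@offCounts@counts)
  msg <- character()
  if (length(object@onCounts@counts) != n ||
      length(object@perSliceDiff) != n)
    msg <- c(msg, "count series and per-slice differences must align")
  if (object@totalOff != sum(object@offCounts@counts) ||
      object@totalOn != sum(object@onCounts@counts))
    msg <- c(msg, "totals must equal the column sums")
  if (object@totalOff > 0L) {
    expect <- 100 * (object@totalOff - object@totalOn) / object@totalOff
    if (abs(expect - object@reductionRatioPct) > 1e-9)
      msg <- c(msg, "reductionRatioPct inconsistent with totals")
  }
  if (length(msg)) msg else TRUE
})

#' Parametric description of the synthetic arch phantom
#'
#' Describes one axial geometry: a uniform background, a horseshoe-shaped
#' arch band (annulus sector), and one dense circular insert emulating a
#' prosthesis. All boundaries are anti-aliased with a 1-pixel linear ramp.
#'
#' @slot sliceDims `(rows, cols)`.
#' @slot nSlices number of identical axial slices.
#' @slot archIntensity,backgroundIntensity,insertIntensity plateau
#'   intensities, requiring insert > arch > background.
#' @slot insertCenter `(row, col)` of the insert disk.
#' @slot insertRadius insert radius in pixels (0 suppresses the disk).
#' @slot seed base random seed for downstream simulation.
#' @seealso [phantomSpec()], [renderPhantom()], [makePair()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(sliceDims = "integer", nSlices = "integer",
                 archIntensity = "numeric", backgroundIntensity = "numeric",
                 insertCenter = "numeric", insertRadius = "numeric",
                 insertIntensity = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  d <- object@sliceDims
  if (length(d) != 2L || any(d < 32L))
    msg <- c(msg, "sliceDims must be two values >= 32")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (!(object@insertIntensity > object@archIntensity &&
        object@archIntensity > object@backgroundIntensity))
    msg <- c(msg, "need insertIntensity > archIntensity > backgroundIntensity")
  if (any(c(object@insertIntensity, object@archIntensity,
            object@backgroundIntensity) < 0) ||
      any(c(object@insertIntensity, object@archIntensity,
            object@backgroundIntensity) > 255))
    msg <- c(msg, "intensities must lie in [0, 255]")
  r <- object@insertRadius; ctr <- object@insertCenter
  if (r < 0) msg <- c(msg, "insertRadius must be >= 0")
  if (ctr[1] - r < 1 || ctr[1] + r > d[1] ||
      ctr[2] - r < 1 || ctr[2] + r > d[2])
    msg <- c(msg, "geometry error: insert disk not fully inside the image")
  if (length(msg)) msg else TRUE
})

#' Parametric description of the radial streak artifacts
#'
#' Streaks are straight bands radiating from an origin (the prosthesis
#' insert) at seeded-random angles that respect a minimum angular
#' separation. Each streak is bipolar, the way beam-hardening streaks
#' appear: a bright core band flanked on both sides by dark shadow bands
#' (photon starvation), so every streak carries both polarities and the
#' same detectable contrast.
#'
#' @slot nStreaks number of streak bands.
#' @slot width core band width in pixels.
#' @slot length radial band length in pixels.
#' @slot brightAmplitude intensity added by the core band.
#' @slot darkAmplitude intensity subtracted by the flanking shadows (both
#'   before clipping to [0, 255]).
#' @slot flankWidth width of each dark flank in pixels (0 disables flanks).
#' @slot minAngularSeparation minimum angle between any two streaks, radians.
#' @seealso [streakSpec()], [addStreaks()]
#' @exportClass StreakSpec
setClass("StreakSpec",
  representation(nStreaks = "integer", width = "numeric", length = "numeric",
                 brightAmplitude = "numeric", darkAmplitude = "numeric",
                 flankWidth = "numeric", minAngularSeparation = "numeric"))

setValidity("StreakSpec", function(object) {
  msg <- character()
  if (object@nStreaks < 0L) msg <- c(msg, "nStreaks must be >= 0")
  if (object@width < 1) msg <- c(msg, "width must be >= 1 pixel")
  if (object@flankWidth < 0) msg <- c(msg, "flankWidth must be >= 0")
  if (object@length <= 0) msg <- c(msg, "length must be positive")
  if (object@minAngularSeparation < 0)
    msg <- c(msg, "minAngularSeparation must be >= 0")
  if (object@nStreaks * object@minAngularSeparation >= 2 * pi)
    msg <- c(msg, "spec error: nStreaks * minAngularSeparation must be < 2*pi")
  if (length(msg)) msg else TRUE
})

#' A simulated MAR-off/MAR-on pair with ground truth
#'
#' @slot pair [StackPair-class]; both stacks share the phantom geometry, the
#'   off stack carries `kOff` streaks and the on stack the first `kOn` of the
#'   same streak angles (MAR modeled as streak-subset removal).
#' @slot kOff,kOn streaks per slice in each stack.
#' @slot trueRatioPct combinatorial ground truth
#'   `100 * (kOff - kOn) / kOff`.
#' @slot angles the streak angles (radians) of the off stack.
#' @slot seed seed that reproduces the pair bit-exactly.
#' @seealso [makePair()], [writeSimulatedPair()]
#' @exportClass SimulatedPair
setClass("SimulatedPair",
  representation(pair = "StackPair", kOff = "integer", kOn = "integer",
                 trueRatioPct = "numeric", angles = "numeric",
                 seed = "integer"))

setValidity("SimulatedPair", function(object) {
  msg <- character()
  if (object@kOn > object@kOff) msg <- c(msg, "kOn must be <= kOff")
  if (object@kOff < 1L) msg <- c(msg, "kOff must be >= 1")
  if (length(object@angles) != object@kOff)
    msg <- c(msg, "angles must have one entry per off-stack streak")
  if (length(msg)) msg else TRUE
})

#' Run configuration tying the pipeline together
#'
#' Serializable to and from a flat `key = value` text file so runs are fully
#' declarative and diffable; see [readRunConfig()].
#'
#' @slot edgeParams [EdgeParams-class] for the detection stage.
#' @slot blankThreshold,minFraction blank-slice trimming parameters: a slice
#'   is blank when fewer than `minFraction` of its pixels exceed
#'   `blankThreshold`.
#' @slot connectivity 4 or 8; pixel connectivity defining one "edge".
#' @slot alpha two-sided significance level for the statistics layer.
#' @seealso [runConfig()], [cmdCount()], [cmdCompare()]
#' @exportClass RunConfig
setClass("RunConfig",
  representation(edgeParams = "EdgeParams", blankThreshold = "numeric",
                 minFraction = "numeric", connectivity = "integer",
                 alpha = "numeric"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@blankThreshold < 0 || object@blankThreshold > 255)
    msg <- c(msg, "blankThreshold must lie in [0, 255]")
  if (!(object@minFraction > 0 && object@minFraction < 1))
    msg <- c(msg, "minFraction must lie in (0, 1)")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a run configuration
#'
#' @param edgeParams an [EdgeParams-class] object.
#' @param blankThreshold intensity above which a pixel counts as object
#'   (default 10 on the 0-255 scale).
#' @param minFraction minimum fraction of object pixels for a slice to be
#'   kept (default 0.005).
#' @param connectivity 4 or 8 (default 8: diagonal runs are continuous lines).
#' @param alpha significance level (default 0.05).
#' @return A [RunConfig-class].
#' @examples
#' runConfig()
#' @export
runConfig <- function(edgeParams = MARedge::edgeParams(), blankThreshold = 10,
                      minFraction = 0.005, connectivity = 8L, alpha = 0.05) {
  new("RunConfig", edgeParams = edgeParams,
      blankThreshold = as.numeric(blankThreshold),
      minFraction = as.numeric(minFraction),
      connectivity = as.integer(connectivity), alpha = as.numeric(alpha))
}
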