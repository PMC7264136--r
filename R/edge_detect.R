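#' @include AllClasses.R
NULL

#' @useDynLib MARedge, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

asSliceMatrix <- function(slice) {
  if (is(slice, "ImageStack")) {
    if (nSlices(slice) != 1L)
      stop("expected a single slice; extract one with getSlice()")
    return(slice@slices[, , 1L])
  }
  if (!is.matrix(slice) || !is.numeric(slice))
    stop("slice must be a numeric matrix or a one-slice ImageStack")
  slice
}

#' Impulse-noise removal stage
#'
#' The modification of the classic Canny pipeline: a 3x3 median filter
#' (reflected borders) applied before Gaussian smoothing. Isolated hot or
#' cold pixels are removed; without this stage each of them survives as a
#' spurious one-pixel edge component and inflates the edge count.
#'
#' @param slice numeric intensity matrix on the [0, 255] scale.
#' @param method `"median3"` or `"none"` (identity).
#' @return the filtered matrix, still within [0, 255].
#' @examples
#' x <- matrix(0, 16, 16); x[8, 8] <- 255
#' max(denoiseSlice(x))   # salt pixel removed -> 0
#' @export
denoiseSlice <- function(slice, method = c("median3", "none")) {
  x <- asSliceMatrix(slice)
  method <- match.arg(method)
  if (method == "none") return(x)
  cpp_median3(x)
}

#' Gaussian smoothing stage
#'
#' Separable convolution with a truncated Gaussian kernel of radius
#' `ceiling(3 * sigma)`, normalized to sum 1, with reflected borders
#' (constant images map to themselves; no artificial border response).
#'
#' @param slice numeric intensity matrix.
#' @param sigma positive Gaussian sigma in pixels.
#' @return smoothed numeric matrix.
#' @export
gaussianSmooth <- function(slice, sigma) {
  x <- asSliceMatrix(slice)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number")
  radius <- ceiling(3 * sigma)
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  cpp_sepconv(x, k)
}

#' Gradient stage
#'
#' Horizontal and vertical derivatives by the 3x3 Sobel operators (reflected
#' borders); magnitude is the Euclidean norm, direction the arctangent of the
#' row derivative over the column derivative in (-pi, pi].
#'
#' @param smoothed numeric matrix (at least 3x3), typically the output of
#'   [gaussianSmooth()].
#' @return list with `magnitude` and `direction` matrices.
#' @export
imageGradient <- function(smoothed) {
  x <- asSliceMatrix(smoothed)
  if (nrow(x) < 3L || ncol(x) < 3L) stop("gradient requires a grid >= 3x3")
  g <- cpp_sobel(x)
  list(magnitude = sqrt(g$gx^2 + g$gy^2), direction = atan2(g$gy, g$gx))
}

#' Non-maximum suppression stage
#'
#' Each pixel's gradient direction is quantized to one of four sectors
#' (0, 45, 90, 135 degrees; boundaries at odd multiples of 22.5 degrees) and
#' the pixel is kept only if its magnitude is `>=` both neighbours along the
#' quantized direction (ties on plateaus are kept; border pixels compare only
#' against in-grid neighbours). Suppressed pixels are set to 0.
#'
#' @param magnitude,direction matrices from [imageGradient()].
#' @return thinned magnitude matrix.
#' @export
nonmaxSuppress <- function(magnitude, direction) {
  if (!identical(dim(magnitude), dim(direction)))
    stop("magnitude and direction grids must have identical dimensions")
  cpp_nms(magnitude, direction)
}

#' Resolve automatic hysteresis thresholds
#'
#' The high threshold is the `highPercentile` quantile of the positive
#' entries of the thinned magnitude grid, using linear interpolation of the
#' empirical distribution function (`quantile(..., type = 4)`, i.e. the
#' h = n*p convention, pinned for cross-implementation reproducibility); the
#' low threshold is `lowHighRatio` times the high one. "Positive" uses a
#' relative floor of `1e-8 * max(magnitude)`: nominally flat regions carry
#' magnitudes at the float rounding level after smoothing, and without the
#' floor those epsilon values would dominate the quantile. The floor scales
#' with the image, so intensity rescaling leaves the decision unchanged.
#'
#' @param magnitude thinned magnitude matrix.
#' @param params an [EdgeParams-class] with `thresholdMode = "auto"`.
#' @return list with `low`, `high` and logical `degenerate` (TRUE when the
#'   grid has no positive magnitude, in which case the caller emits an empty
#'   edge map).
#' @export
resolveThresholds <- function(magnitude, params) {
  stopifnot(is(params, "EdgeParams"))
  if (params@thresholdMode != "auto")
    stop("resolveThresholds applies only to auto threshold mode")
  tol <- 1e-8 * max(magnitude)
  pos <- magnitude[magnitude > tol]
  if (length(pos) == 0L)
    return(list(low = NA_real_, high = NA_real_, degenerate = TRUE))
  high <- unname(stats::quantile(pos, params@highPercentile, type = 4))
  list(low = params@lowHighRatio * high, high = high, degenerate = FALSE)
}

#' Hysteresis thresholding stage
#'
#' Pixels with magnitude `>= high` are strong; pixels in `[low, high)` are
#' weak; the final edges are the strong pixels plus every weak pixel
#' 8-connected to a strong pixel through chains of weak/strong pixels.
#'
#' @param thinned thinned magnitude matrix.
#' @param low,high thresholds with `low < high`.
#' @return logical edge matrix.
#' @export
hysteresis <- function(thinned, low, high) {
  if (!(is.finite(low) && is.finite(high) && low < high))
    stop("require finite thresholds with low < high")
  cpp_hysteresis(thinned, low, high)
}

#' Detect edges in one slice
#'
#' The full modified Canny pipeline: noise removal, Gaussian smoothing,
#' Sobel gradient, non-maximum suppression, threshold resolution and
#' hysteresis. Deterministic for fixed input and parameters.
#'
#' @param slice numeric intensity matrix on the [0, 255] scale (or a
#'   one-slice [ImageStack-class]).
#' @param params an [EdgeParams-class]; see [edgeParams()].
#' @return an [EdgeMap-class]; `paramsUsed` carries the materialized
#'   thresholds.
#' @examples
#' disk <- outer(1:32, 1:32, function(r, c) {
#'   ifelse((r - 16)^2 + (c - 16)^2 <= 25, 200, 0)
#' })
#' em <- detectEdges(disk, edgeParams())
#' countEdges(em)   # one closed contour
#' @export
detectEdges <- function(slice, params = edgeParams()) {
  x <- asSliceMatrix(slice)
  stopifnot(is(params, "EdgeParams"))
  validObject(params)
  den <- denoiseSlice(x, params@denoiseMethod)
  sm <- gaussianSmooth(den, params@gaussianSigma)
  g <- imageGradient(sm)
  thin <- nonmaxSuppress(g$magnitude, g$direction)
  if (params@thresholdMode == "auto") {
    thr <- resolveThresholds(thin, params)
    if (thr$degenerate) {
      used <- params
      return(new("EdgeMap",
                 pixels = matrix(FALSE, nrow(x), ncol(x)),
                 paramsUsed = used))
    }
    low <- thr$low; high <- thr$high
  } else {
    low <- params@lowThreshold; high <- params@highThreshold
  }
  used <- params
  used@lowThreshold <- low
  used@highThreshold <- high
  new("EdgeMap", pixels = hysteresis(thin, low, high), paramsUsed = used)
}
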