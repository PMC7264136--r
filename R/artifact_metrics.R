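#' @include AllClasses.R edge_detect.R
NULL

#' Count edges in a binary edge map
#'
#' An edge is "a continuous line with no breaks": one connected component of
#' edge pixels. The default connectivity is 8 so that diagonal pixel runs,
#' which are visually continuous lines, count as a single edge; 4 is exposed
#' for comparison.
#'
#' @param map an [EdgeMap-class] or a logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return non-negative integer component count; an empty map gives 0.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE
#' countEdges(m)       # one diagonal run under 8-connectivity
#' countEdges(m, 4)    # fragments under 4-connectivity
#' @export
countEdges <- function(map, connectivity = 8L) {
  px <- if (is(map, "EdgeMap")) map@pixels else map
  if (!is.logical(px) || !is.matrix(px))
    stop("map must be an EdgeMap or a logical matrix")
  cpp_count_components(px, as.integer(connectivity))
}

#' Per-slice edge counts of a stack
#'
#' Applies [detectEdges()] then [countEdges()] to every slice, preserving
#' slice order. Intended to run on a trimmed stack (see
#' [trimBlankSlices()]).
#'
#' @param stack an [ImageStack-class].
#' @param params an [EdgeParams-class].
#' @param connectivity 4 or 8.
#' @return an [EdgeCountSeries-class] labelled like the stack.
#' @export
countStack <- function(stack, params = edgeParams(), connectivity = 8L) {
  stopifnot(is(stack, "ImageStack"))
  n <- nSlices(stack)
  counts <- vapply(seq_len(n) - 1L, function(i)
    countEdges(detectEdges(getSlice(stack, i), params), connectivity),
    integer(1))
  new("EdgeCountSeries", counts = counts, marState = stack@marState,
      prosthesis = stack@prosthesis, voxelMM = stack@voxelMM,
      kvp = stack@kvp)
}

#' Edge reduction ratio
#'
#' The headline MAR-efficacy metric:
#' `100 * (edges in MAR-off - edges in MAR-on) / edges in MAR-off`.
#' Negative values are admitted (MAR-on may contain more edges).
#'
#' @param totalOff positive edge total of the MAR-off stack.
#' @param totalOn non-negative edge total of the MAR-on stack.
#' @return the ratio in percent.
#' @examples
#' reductionRatio(1000, 500)   # 50
#' reductionRatio(200, 220)    # -10
#' @export
reductionRatio <- function(totalOff, totalOn) {
  if (any(totalOff <= 0))
    stop("undefined ratio: MAR-off edge total must be positive")
  if (any(totalOn < 0)) stop("MAR-on edge total must be non-negative")
  100 * (totalOff - totalOn) / totalOff
}

#' Per-slice count differences between paired stacks
#'
#' Element-wise off minus on, paired by slice index, with the mean and
#' sample standard deviation (n-1 denominator) attached -- the quantities
#' summarized as mean +/- SD per scan condition.
#'
#' @param off,on [EdgeCountSeries-class] objects or integer vectors of equal
#'   length.
#' @return list with `diff` (integer vector), `mean` and `sd`.
#' @export
sliceDifferences <- function(off, on) {
  a <- if (is(off, "EdgeCountSeries")) off@counts else as.integer(off)
  b <- if (is(on, "EdgeCountSeries")) on@counts else as.integer(on)
  if (length(a) != length(b))
    stop(sprintf("pairing error: %d vs %d slices", length(a), length(b)))
  d <- a - b
  list(diff = d, mean = mean(d),
       sd = if (length(d) > 1L) stats::sd(d) else NA_real_)
}

#' Analyze a MAR-off/MAR-on pair
#'
#' Computes both per-slice edge-count series, per-slice differences, stack
#' totals and the reduction ratio on the totals. Deterministic for fixed
#' input and parameters.
#'
#' @param pair a [StackPair-class] (or [SimulatedPair-class]).
#' @param params an [EdgeParams-class].
#' @param connectivity 4 or 8.
#' @return a [ReductionReport-class].
#' @export
analyzePair <- function(pair, params = edgeParams(), connectivity = 8L) {
  if (is(pair, "SimulatedPair")) pair <- pair@pair
  stopifnot(is(pair, "StackPair"))
  validObject(pair)
  offC <- countStack(pair@offStack, params, connectivity)
  onC <- countStack(pair@onStack, params, connectivity)
  d <- sliceDifferences(offC, onC)
  totOff <- sum(offC@counts); totOn <- sum(onC@counts)
  new("ReductionReport", offCounts = offC, onCounts = onC,
      perSliceDiff = d$diff, totalOff = totOff, totalOn = totOn,
      reductionRatioPct = reductionRatio(totOff, totOn),
      meanDiff = d$mean, sdDiff = d$sd)
}

#' Per-slice edge reduction ratios
#'
#' `100 * (off_i - on_i) / off_i` per slice; these per-slice ratios are the
#' samples entering the across-prosthesis Welch ANOVA. Slices with a zero
#' MAR-off count yield `NA` (the ratio is undefined there).
#'
#' @param report a [ReductionReport-class].
#' @return numeric vector, one ratio per slice.
#' @export
perSliceRatios <- function(report) {
  stopifnot(is(report, "ReductionReport"))
  off <- report@offCounts@counts
  on <- report@onCounts@counts
  ifelse(off > 0L, 100 * (off - on) / off, NA_real_)
}
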