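#' @include AllClasses.R image_io.R
NULL

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Construct a phantom specification
#'
#' Defaults emulate a desk-scale dental-arch slice: 256x256 pixels, 10
#' identical axial slices, near-black background (20), a soft-tissue-like
#' arch band (120) and one dense prosthesis insert (250, radius 8) at the
#' arch centre, from which streaks later radiate.
#'
#' @param sliceDims `(rows, cols)` (default `c(256, 256)`).
#' @param nSlices slices per stack (default 10).
#' @param backgroundIntensity,archIntensity,insertIntensity plateau
#'   intensities (defaults 20, 120, 250).
#' @param insertCenter `(row, col)`; default centred on the arch.
#' @param insertRadius insert radius in pixels (default 8; 0 suppresses the
#'   disk).
#' @param seed base seed (default 1).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(sliceDims = c(256L, 256L), nSlices = 10L,
                        backgroundIntensity = 20, archIntensity = 120,
                        insertIntensity = 250,
                        insertCenter = NULL, insertRadius = 8,
                        seed = 1L) {
  sliceDims <- as.integer(sliceDims)
  if (is.null(insertCenter))
    insertCenter <- c(round(0.59 * sliceDims[1]), round(0.5 * sliceDims[2]))
  new("PhantomSpec", sliceDims = sliceDims, nSlices = as.integer(nSlices),
      archIntensity = as.numeric(archIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      insertCenter = as.numeric(insertCenter),
      insertRadius = as.numeric(insertRadius),
      insertIntensity = as.numeric(insertIntensity),
      seed = as.integer(seed))
}

#' Construct a streak specification
#'
#' Each streak is a bipolar band: a bright core with two dark flanking
#' shadows, the joint bright/dark appearance of beam-hardening streaks.
#' Defaults: core width 4 px, flanks 3 px, radial length 45 px (bands end
#' well inside the default arch so streak contours stay disjoint from the
#' arch contour), core amplitude 100 (the arch-over-background contrast, so
#' streaks and anatomy present the same edge strength) and shadow depth 20
#' (the full swing available above the default background before clipping).
#'
#' @param nStreaks number of radial streak bands.
#' @param width core band width in pixels (default 4).
#' @param length radial band length in pixels (default 45).
#' @param brightAmplitude intensity added by the core (default 100).
#' @param darkAmplitude intensity subtracted by the flanks (default 20).
#' @param flankWidth width of each dark flank in pixels (default 3; 0
#'   disables the shadows).
#' @param minAngularSeparation minimum angle between streaks in radians
#'   (default 0.45, keeping bands disjoint from their neighbours along their
#'   whole length at the default start radius).
#' @return a [StreakSpec-class].
#' @export
streakSpec <- function(nStreaks, width = 4, length = 45,
                       brightAmplitude = 100, darkAmplitude = 20,
                       flankWidth = 3, minAngularSeparation = 0.45) {
  new("StreakSpec", nStreaks = as.integer(nStreaks),
      width = as.numeric(width), length = as.numeric(length),
      brightAmplitude = as.numeric(brightAmplitude),
      darkAmplitude = as.numeric(darkAmplitude),
      flankWidth = as.numeric(flankWidth),
      minAngularSeparation = as.numeric(minAngularSeparation))
}

#' Render the arch phantom
#'
#' Each slice contains the background, a horseshoe-shaped arch band (an
#' annulus sector spanning 210 degrees, opening towards the bottom of the
#' image) and the dense insert disk; all boundaries carry a 1-pixel linear
#' anti-aliasing ramp so each closed boundary yields one continuous edge
#' contour instead of a stair-cased fragment set. Slices are identical.
#'
#' @param spec a [PhantomSpec-class].
#' @return an [ImageStack-class] with MAR state `"off"` and prosthesis
#'   `"synthetic"`.
#' @export
renderPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  nr <- spec@sliceDims[1]; nc <- spec@sliceDims[2]
  # arch: annulus sector centred where the insert sits by default
  acR <- round(0.59 * nr); acC <- round(0.5 * nc)
  rIn <- 0.30 * min(nr, nc); rOut <- 0.41 * min(nr, nc)
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dx <- col - acC; dy <- acR - row            # y axis pointing up
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)                      # (-pi, pi]
  # sector from -15 to 195 degrees (opening at the bottom); the angular
  # distance to the sector boundary is converted to an arc length so the
  # end caps get the same 1-pixel ramp as the radial boundaries
  lo <- -15 * pi / 180; hi <- 195 * pi / 180
  th <- ifelse(theta < lo, theta + 2 * pi, theta)
  angDist <- pmin(th - lo, hi - th)           # >0 inside the sector
  signedArch <- pmin(d - rIn, rOut - d, angDist * pmax(d, 1))
  covArch <- clamp01(signedArch + 0.5)
  img <- spec@backgroundIntensity +
    covArch * (spec@archIntensity - spec@backgroundIntensity)
  if (spec@insertRadius > 0) {
    d2 <- sqrt((row - spec@insertCenter[1])^2 + (col - spec@insertCenter[2])^2)
    covIns <- clamp01(spec@insertRadius - d2 + 0.5)
    img <- img + covIns * (spec@insertIntensity - img)
  }
  img <- pmin(pmax(img, 0), 255)
  imageStack(array(img, dim = c(nr, nc, spec@nSlices)),
             marState = "off", prosthesis = "synthetic")
}

#' Draw streak angles
#'
#' Draws `n` angles uniformly over the configurations that respect the
#' minimum circular separation, using the spacing construction: sample `n`
#' points on the circle shortened by the total required separation, sort,
#' re-insert one separation between consecutive points, rotate by a random
#' offset, and finally apply a seeded random permutation so that the leading
#' subset used by the MAR-on stack is a random subset rather than a
#' contiguous arc. Deterministic per seed; feasible whenever
#' `n * minSep < 2*pi`.
#'
#' @param n number of angles.
#' @param minSep minimum circular separation in radians.
#' @param seed RNG seed.
#' @return numeric vector of `n` angles in radians.
#' @export
streakAngles <- function(n, minSep, seed) {
  if (n * minSep >= 2 * pi)
    stop("spec error: angular separation infeasible for ", n, " streaks")
  if (n == 0L) return(numeric(0))
  withSeed(seed, {
    free <- 2 * pi - n * minSep
    u <- sort(stats::runif(n, 0, free))
    a <- (u + minSep * (seq_len(n) - 1L) + stats::runif(1, 0, 2 * pi)) %%
      (2 * pi)
    a[sample.int(n)]
  })
}

# Additive streak field for one slice geometry: bipolar bands radiating
# from the origin between radii startRadius and startRadius + length, with
# 1-pixel linear ramps on all band boundaries. Each band adds
# +brightAmplitude over its core (width `width`) and -darkAmplitude over
# the two flanks (width `flankWidth` each side of the core).
streakField <- function(dims, streaks, origin, angles, startRadius) {
  nr <- dims[1]; nc <- dims[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  relx <- col - origin[2]; rely <- origin[1] - row   # y up
  field <- matrix(0, nr, nc)
  for (i in seq_along(angles)) {
    ux <- cos(angles[i]); uy <- sin(angles[i])
    t <- relx * ux + rely * uy
    p <- abs(-relx * uy + rely * ux)
    covT <- clamp01(pmin(t - startRadius,
                         startRadius + streaks@length - t) + 0.5)
    covCore <- clamp01(streaks@width / 2 - p + 0.5)
    covFlank <- clamp01(streaks@width / 2 + streaks@flankWidth - p + 0.5) -
      covCore
    field <- field + covT * (streaks@brightAmplitude * covCore -
                             streaks@darkAmplitude * covFlank)
  }
  field
}

#' Add radial streak artifacts to a stack
#'
#' Draws `nStreaks` straight bipolar bands (bright core, dark flanking
#' shadows) radiating from `origin` at seeded-random angles respecting the
#' minimum angular separation, added to the underlying image and clipped to
#' [0, 255].
#' The same angles are applied to every slice: a fixed prosthesis casts the
#' same streak pattern through contiguous axial slices, so the artifact is
#' rigid across the stack.
#'
#' @param stack an [ImageStack-class].
#' @param streaks a [StreakSpec-class].
#' @param origin `(row, col)` the streaks radiate from (default: image
#'   centre of mass of the brightest structure is not inferred; pass the
#'   insert centre).
#' @param seed RNG seed for the angles.
#' @param startRadius radial distance at which bands start, in pixels
#'   (default 16: outside the default insert so streak contours stay
#'   disjoint from the insert contour).
#' @param angles optional explicit angles (radians), bypassing sampling.
#' @return the stack with streaks applied.
#' @export
addStreaks <- function(stack, streaks, origin, seed = 1L, startRadius = 16,
                       angles = NULL) {
  stopifnot(is(stack, "ImageStack"), is(streaks, "StreakSpec"))
  validObject(streaks)
  d <- sliceDims(stack)
  if (origin[1] < 1 || origin[1] > d[1] || origin[2] < 1 || origin[2] > d[2])
    stop("origin must lie inside the image")
  if (is.null(angles))
    angles <- streakAngles(streaks@nStreaks, streaks@minAngularSeparation,
                           seed)
  if (length(angles) == 0L) return(stack)
  field <- streakField(d, streaks, origin, angles, startRadius)
  out <- stack
  for (i in seq_len(nSlices(stack)))
    out@slices[, , i] <- pmin(pmax(stack@slices[, , i] + field, 0), 255)
  out
}

#' Add Gaussian noise to a stack
#'
#' Seeded additive Gaussian noise, drawn independently per pixel and slice,
#' clipped to [0, 255]. `sigma = 0` is the exact identity.
#'
#' @param stack an [ImageStack-class].
#' @param sigma noise standard deviation in intensity units (>= 0).
#' @param seed RNG seed.
#' @return the noisy stack.
#' @export
addNoise <- function(stack, sigma, seed = 1L) {
  stopifnot(is(stack, "ImageStack"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(stack)
  out <- stack
  withSeed(seed, {
    noise <- array(stats::rnorm(length(stack@slices), 0, sigma),
                   dim = dim(stack@slices))
    out@slices <- pmin(pmax(stack@slices + noise, 0), 255)
  })
  out
}

#' Edge-detection parameters for phantom validation
#'
#' The validation configuration used for simulated phantoms: the pipeline
#' defaults with fixed hysteresis thresholds placed in the wide gap of the
#' phantom's gradient-magnitude spectrum. A piecewise-constant phantom
#' concentrates its non-maximum-suppressed gradient magnitudes on a few
#' crest plateaus (about 40 for the 20-intensity steps of the dark shadows,
#' about 200 for the 100-intensity steps of arch and streak cores, higher
#' for the insert); a percentile-based threshold necessarily lands on one
#' of those plateaus and turns the detection of a whole contour family into
#' a knife-edge decision, whereas thresholds fixed in the empty band
#' between the plateaus (low 60, high 150 by default) classify every
#' contour with a wide margin. Automatic thresholds remain the default for
#' real scans, whose magnitude spectra are continuous.
#'
#' @param lowThreshold,highThreshold fixed hysteresis thresholds
#'   (defaults 60 and 150).
#' @param ... further arguments passed to [edgeParams()].
#' @return an [EdgeParams-class] in fixed threshold mode.
#' @seealso [makePair()], [analyzePair()]
#' @export
phantomEdgeParams <- function(lowThreshold = 60, highThreshold = 150, ...) {
  edgeParams(thresholdMode = "fixed", lowThreshold = lowThreshold,
             highThreshold = highThreshold, ...)
}

#' Simulate a matched MAR-off/MAR-on pair with ground truth
#'
#' Renders the same phantom twice; the off stack receives `kOff` streaks and
#' the on stack the same leading `kOn` streak angles -- MAR is modeled as
#' streak-subset removal with identical residual geometry, which provides
#' exact combinatorial ground truth (`trueRatioPct = 100 (kOff - kOn) /
#' kOff`) that a real reconstruction cannot. Noise is drawn independently
#' per stack from seeds derived from `seed`; the same seed reproduces the
#' pair bit-exactly.
#'
#' @param spec a [PhantomSpec-class].
#' @param streaks a [StreakSpec-class]; its `nStreaks` is ignored in favour
#'   of `kOff`/`kOn`.
#' @param kOff streaks per slice in the MAR-off stack (>= 1).
#' @param kOn streaks per slice in the MAR-on stack (0 <= kOn <= kOff).
#' @param noiseSigma Gaussian noise SD (default 0, noise-free).
#' @param seed RNG seed (default: the spec's seed).
#' @param startRadius passed to [addStreaks()].
#' @return a [SimulatedPair-class].
#' @examples
#' sim <- makePair(phantomSpec(nSlices = 2L), streakSpec(10), kOff = 10,
#'                 kOn = 4, seed = 7)
#' sim@trueRatioPct
#' @export
makePair <- function(spec, streaks = streakSpec(10), kOff = 10L, kOn = 4L,
                     noiseSigma = 0, seed = spec@seed, startRadius = 16) {
  stopifnot(is(spec, "PhantomSpec"), is(streaks, "StreakSpec"))
  kOff <- as.integer(kOff); kOn <- as.integer(kOn)
  if (kOff < 1L) stop("kOff must be >= 1")
  if (kOn > kOff) stop("parameter error: kOn must be <= kOff")
  if (kOn < 0L) stop("kOn must be >= 0")
  seed <- as.integer(seed)
  base <- renderPhantom(spec)
  angles <- streakAngles(kOff, streaks@minAngularSeparation, seed)
  origin <- spec@insertCenter
  off <- addStreaks(base, streaks, origin, startRadius = startRadius,
                    angles = angles)
  on <- addStreaks(base, streaks, origin, startRadius = startRadius,
                   angles = angles[seq_len(kOn)])
  if (noiseSigma > 0) {
    off <- addNoise(off, noiseSigma, seed = 2L * seed + 1L)
    on <- addNoise(on, noiseSigma, seed = 2L * seed + 2L)
  }
  on@marState <- "on"
  pair <- pairStacks(off, on)
  new("SimulatedPair", pair = pair, kOff = kOff, kOn = kOn,
      trueRatioPct = 100 * (kOff - kOn) / kOff, angles = angles,
      seed = seed)
}

#' Write a simulated pair to disk
#'
#' Emits `off/` and `on/` PNG slice directories consumable by [readStack()]
#' plus a `ground_truth.json` sidecar with the streak counts, angles, seed
#' and true reduction ratio.
#'
#' @param sim a [SimulatedPair-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSimulatedPair <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedPair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeStack(sim@pair@offStack, file.path(dir, "off"))
  writeStack(sim@pair@onStack, file.path(dir, "on"))
  jsonlite::write_json(
    list(k_off = sim@kOff, k_on = sim@kOn, seed = sim@seed,
         angles_rad = sim@angles, true_ratio_pct = sim@trueRatioPct),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}
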