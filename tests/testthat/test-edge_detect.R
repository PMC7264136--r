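# The modified Canny stages: fixed examples first, then brute-force oracle
# equivalence on random grids (the larger sweeps live in the acceptance
# tests).

test_that("median denoising removes impulses and preserves constants", {
  const <- matrix(100, 12, 12)
  expect_equal(denoiseSlice(const, "median3"), const)
  salt <- matrix(0, 12, 12); salt[6, 6] <- 255
  expect_equal(max(denoiseSlice(salt, "median3")), 0)
  expect_identical(denoiseSlice(salt, "none"), salt)
  expect_error(denoiseSlice(salt, "blur"), "arg")
})

test_that("median filter equals the per-pixel sort oracle", {
  set.seed(101)
  for (i in 1:8) {
    x <- randomGrid(16)
    expect_equal(denoiseSlice(x, "median3"), oracleMedian3(x))
  }
})

test_that("gaussian smoothing conserves constants and impulse mass", {
  const <- matrix(100, 16, 16)
  expect_equal(gaussianSmooth(const, 1.4), const, tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussianSmooth(imp, 1.4)
  expect_equal(sum(sm), 1, tolerance = 1e-12)        # mass conservation
  expect_equal(which.max(sm), 11L + 10L * 21L)       # centred
  # proportional to the separable 2-D gaussian
  rad <- ceiling(3 * 1.4)
  k <- exp(-((-rad:rad)^2) / (2 * 1.4^2)); k <- k / sum(k)
  expect_equal(sm[11 + (-rad:rad), 11 + (-rad:rad)], outer(k, k),
               tolerance = 1e-12)
  expect_error(gaussianSmooth(const, 0), "positive")
})

test_that("gaussian smoothing equals the dense 2-D convolution oracle", {
  set.seed(102)
  for (sigma in c(0.8, 1.4)) {
    x <- randomGrid(20)
    rad <- ceiling(3 * sigma)
    k <- exp(-((-rad:rad)^2) / (2 * sigma^2)); k <- k / sum(k)
    expect_equal(gaussianSmooth(x, sigma), oracleConv2(x, k),
                 tolerance = 1e-9)
  }
})

test_that("gradient matches the Sobel stencil oracle and step geometry", {
  step <- cbind(matrix(0, 16, 8), matrix(255, 16, 8))
  g <- imageGradient(step)
  expect_equal(which.max(colSums(g$magnitude)), 8L, tolerance = 1)
  inner <- g$direction[5:12, 8:9]
  expect_true(all(abs(inner) < 1e-9))                # horizontal gradient
  expect_equal(imageGradient(matrix(7, 10, 10))$magnitude,
               matrix(0, 10, 10), tolerance = 1e-12)
  set.seed(103)
  for (i in 1:5) {
    x <- randomGrid(16)
    o <- oracleSobel(x)
    g <- imageGradient(x)
    expect_equal(g$magnitude, o$magnitude, tolerance = 1e-9)
    expect_equal(g$direction, o$direction, tolerance = 1e-9)
  }
})

test_that("non-maximum suppression keeps ridges and plateau ties", {
  ridge <- matrix(0, 9, 9); ridge[5, ] <- 10
  dir <- matrix(pi / 2, 9, 9)       # vertical gradient across the ridge
  expect_equal(nonmaxSuppress(ridge, dir), ridge)
  plateau <- matrix(3, 6, 6)
  expect_equal(nonmaxSuppress(plateau, matrix(0, 6, 6)), plateau)
  expect_error(nonmaxSuppress(plateau, matrix(0, 5, 6)), "dimensions")
})

test_that("non-maximum suppression equals the per-pixel sector oracle", {
  set.seed(104)
  for (i in 1:10) {
    x <- randomGrid(14)
    g <- imageGradient(x)
    expect_equal(nonmaxSuppress(g$magnitude, g$direction),
                 oracleNms(g$magnitude, g$direction), tolerance = 0)
  }
})

test_that("auto thresholds follow the pinned quantile definition", {
  p <- edgeParams()
  thr <- resolveThresholds(matrix(1:100, 10, 10), p)
  expect_false(thr$degenerate)
  expect_equal(thr$high, 70)
  expect_equal(thr$low, 28)
  const <- matrix(5, 8, 8)
  expect_equal(resolveThresholds(const, p)$high, 5)
  expect_true(resolveThresholds(matrix(0, 8, 8), p)$degenerate)
  set.seed(105)
  for (i in 1:10) {
    m <- randomGrid(12, lo = 0.5, hi = 9)
    thr <- resolveThresholds(m, p)
    expect_equal(thr$high, oracleQuantile4(as.vector(m), 0.7),
                 tolerance = 1e-12)
  }
})

test_that("hysteresis follows strong seeds through weak chains", {
  m <- matrix(0, 8, 8)
  expect_equal(sum(hysteresis(m + 0.1, 1, 2)), 0)    # all below low
  m[4, 2] <- 10                                      # strong seed
  m[cbind(3:7, 3:7)] <- 5                            # weak diagonal chain
  em <- hysteresis(m, 4, 9)
  expect_equal(sum(em), 6)                           # seed + 5 weak
  m2 <- m; m2[7, 7] <- 3                             # below low: excluded
  expect_equal(sum(hysteresis(m2, 4, 9)), 5)
  expect_error(hysteresis(m, 5, 5), "low")
})

test_that("hysteresis equals the breadth-first flood oracle", {
  set.seed(106)
  for (i in 1:10) {
    m <- randomGrid(14, lo = 0, hi = 10)
    expect_identical(hysteresis(m, 3, 7), oracleHysteresis(m, 3, 7))
  }
})

test_that("detectEdges is deterministic and empty on uniform images", {
  p <- edgeParams()
  uni <- matrix(42, 32, 32)
  expect_equal(sum(detectEdges(uni, p)@pixels), 0)
  disk <- diskImage(32, 5)
  e1 <- detectEdges(disk, p); e2 <- detectEdges(disk, p)
  expect_identical(e1@pixels, e2@pixels)
  expect_equal(countEdges(e1), 1)                    # one closed contour
  expect_identical(dim(e1@pixels), dim(disk))
  expect_true(e1@paramsUsed@lowThreshold < e1@paramsUsed@highThreshold)
})

test_that("detectEdges commutes with 90-degree rotation on a disk", {
  img <- diskImage(33, 7, center = c(14, 20))
  p <- edgeParams()
  rot90 <- function(m) t(m)[ncol(m):1, ]
  em <- detectEdges(img, p)@pixels
  emRot <- detectEdges(rot90(img), p)@pixels
  expect_identical(emRot, rot90(em))
})

test_that("auto-threshold detection is invariant under intensity scaling", {
  p <- edgeParams()
  base <- diskImage(32, 6, value = 40)
  scaled <- diskImage(32, 6, value = 250)
  expect_identical(detectEdges(base, p)@pixels,
                   detectEdges(scaled, p)@pixels)
})

test_that("edge pixel count grows with disk radius", {
  p <- edgeParams()
  counts <- vapply(3:10, function(r)
    sum(detectEdges(diskImage(32, r), p)@pixels), numeric(1))
  expect_true(all(diff(counts) >= 0))
})
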