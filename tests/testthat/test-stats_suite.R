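# Statistical layer: Shapiro-Wilk screen, Welch ANOVA, Games-Howell and
# Welch t, checked against formula transcriptions, a quadrature
# studentized-range CDF, and values frozen from an independent Python
# implementation (scipy / pingouin) on the literal data below.

test_that("shapiro screen validates input and is affine invariant", {
  expect_error(shapiroWilk(rep(1, 10)), "degenerate")
  expect_error(shapiroWilk(c(1, 2)), "sample size")
  set.seed(301)
  x <- rnorm(25)
  expect_equal(shapiroWilk(3.2 * x + 11)$W, shapiroWilk(x)$W,
               tolerance = 1e-12)
  expect_true(shapiroWilk(x)$advisory)
  expect_false(shapiroWilk(rnorm(40))$advisory)
})

test_that("shapiro W and p match the frozen reference values", {
  for (fz in frozenShapiro) {
    got <- shapiroWilk(fz$x)
    expect_equal(got$W, fz$W, tolerance = 1e-6)
    expect_equal(got$p.value, fz$p, tolerance = 1e-6)
  }
})

test_that("shapiro p-values are uniform under the null", {
  set.seed(302)
  pvals <- replicate(2000, shapiroWilk(rnorm(20))$p.value)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("welch anova handles degenerate and identical designs", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- welchAnova(g)
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1, tolerance = 1e-12)
  expect_equal(res$df1, 2)
  expect_error(welchAnova(list(a = 1:3)), "at least 2")
  expect_error(welchAnova(list(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero variance")
})

test_that("two-group welch anova F equals the squared welch t", {
  set.seed(303)
  for (i in 1:25) {
    a <- rnorm(sample(5:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:20, 1), mean = runif(1, -1, 1))
    f <- welchAnova(list(a = a, b = b))
    t <- welchTTest(a, b)
    expect_equal(f$F, t$t^2, tolerance = 1e-9)
    expect_equal(f$p.value, t$p.value, tolerance = 1e-9)
  }
})

test_that("welch anova matches the formula oracle and frozen references", {
  set.seed(304)
  for (i in 1:20) {
    g <- lapply(setNames(sample(5:25, 4), paste0("g", 1:4)), function(n)
      rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3)))
    got <- welchAnova(g)
    want <- oracleWelchAnova(g)
    expect_equal(got$F, want$F, tolerance = 1e-9)
    expect_equal(got$df2, want$df2, tolerance = 1e-9)
    expect_equal(got$p.value, want$p, tolerance = 1e-9)
  }
  for (fz in frozenWelchAnova) {
    got <- welchAnova(fz$groups)
    expect_equal(got$F, fz$F, tolerance = 1e-6)
    expect_equal(got$df2, fz$df2, tolerance = 1e-6)
    expect_equal(got$p.value, fz$p, tolerance = 1e-6)
  }
})

test_that("welch t is antisymmetric and matches oracles", {
  a <- c(1.2, 0.4, -0.3, 2.2, 0.9)
  expect_equal(welchTTest(a, a)$t, 0)
  expect_equal(welchTTest(a, a)$p.value, 1)
  b <- c(0.1, -0.8, 1.4, 0.6, 2.5, -1.2)
  fwd <- welchTTest(a, b); rev <- welchTTest(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p.value, rev$p.value)
  expect_error(welchTTest(c(1, 1), c(1, 1)), "degenerate")
  set.seed(305)
  for (i in 1:20) {
    a <- rnorm(sample(4:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(4:20, 1), mean = 0.5)
    got <- welchTTest(a, b)
    want <- oracleWelchT(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p.value, want$p, tolerance = 1e-9)
  }
  for (fz in frozenWelchT) {
    got <- welchTTest(fz$a, fz$b)
    expect_equal(got$t, fz$t, tolerance = 1e-6)
    expect_equal(got$df, fz$df, tolerance = 1e-6)
    expect_equal(got$p.value, fz$p, tolerance = 1e-6)
  }
})

test_that("games-howell is symmetric and saturates for identical groups", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(0, 2, 4, 6))
  res <- gamesHowell(g)
  ab <- res[res$group_a == "a" & res$group_b == "b", ]
  expect_equal(ab$mean_diff, 0)
  expect_equal(ab$p.adjusted, 1, tolerance = 1e-9)
  # order swap: same p, negated difference
  res2 <- gamesHowell(list(b = g$b, a = g$a, c = g$c))
  ba <- res2[res2$group_a == "b" & res2$group_b == "a", ]
  expect_equal(ba$mean_diff, -ab$mean_diff)
  expect_equal(ba$p.adjusted, ab$p.adjusted, tolerance = 1e-12)
  expect_equal(nrow(res), 3)   # k(k-1)/2 pairs
})

test_that("games-howell p-values match quadrature and frozen references", {
  set.seed(306)
  for (i in 1:6) {
    g <- lapply(setNames(sample(6:15, 3), c("a", "b", "c")), function(n)
      rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2.5)))
    res <- gamesHowell(g)
    for (j in seq_len(nrow(res))) {
      want <- oracleGamesHowellP(g[[res$group_a[j]]], g[[res$group_b[j]]],
                                 k = 3)
      expect_equal(res$p.adjusted[j], want, tolerance = 1e-4)
    }
  }
  res <- gamesHowell(frozenGamesHowell$groups)
  fz <- frozenGamesHowell$pairs
  for (j in seq_len(nrow(fz))) {
    row <- res[res$group_a == fz$a[j] & res$group_b == fz$b[j], ]
    expect_equal(row$mean_diff, fz$diff[j], tolerance = 1e-6)
    expect_equal(row$df, fz$df[j], tolerance = 1e-6)
    expect_equal(row$p.adjusted, fz$p[j], tolerance = 1e-4)
  }
})

test_that("two-group games-howell agrees with the studentized-range
           transform of the welch t", {
  set.seed(307)
  for (i in 1:10) {
    a <- rnorm(8, sd = 2); b <- rnorm(12, mean = 1)
    gh <- gamesHowell(list(a = a, b = b))
    tt <- welchTTest(a, b)
    p <- ptukey(sqrt(2) * abs(tt$t), nmeans = 2, df = tt$df,
                lower.tail = FALSE)
    expect_equal(gh$p.adjusted, p, tolerance = 1e-9)
    expect_equal(gh$q, sqrt(2) * abs(tt$t), tolerance = 1e-9)
  }
})

test_that("factorial comparison reproduces the 2x2 margin structure", {
  set.seed(308)
  same <- rnorm(12)
  tab <- expand.grid(voxel = c(0.2, 0.3), kvp = c(70, 100))
  table <- do.call(rbind, lapply(seq_len(4), function(j)
    data.frame(voxel = tab$voxel[j], kvp = tab$kvp[j], value = same)))
  res <- compareConditions(table)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p.value == 1))
  expect_equal(sum(res$factor_tested == "kvp"), 2)
  expect_equal(sum(res$factor_tested == "voxel"), 2)
  # missing cell
  expect_error(compareConditions(table[table$kvp == 70, ]),
               "incomplete design")
  expect_error(compareConditions(table[!(table$voxel == 0.2 &
                                         table$kvp == 70), ][1:30, ]),
               "incomplete")
})

test_that("a voxel-size effect is detected on the voxel margins only", {
  set.seed(309)
  n <- 30
  mk <- function(shift) rnorm(n, mean = shift, sd = 1)
  table <- rbind(
    data.frame(voxel = 0.2, kvp = 70,  value = mk(3)),
    data.frame(voxel = 0.2, kvp = 100, value = mk(3)),
    data.frame(voxel = 0.3, kvp = 70,  value = mk(0)),
    data.frame(voxel = 0.3, kvp = 100, value = mk(0)))
  res <- compareConditions(table)
  vox <- res[res$factor_tested == "voxel", ]
  kvp <- res[res$factor_tested == "kvp", ]
  expect_true(all(vox$significant))
  expect_false(any(kvp$significant))
})
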