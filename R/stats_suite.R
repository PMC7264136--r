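#' @include AllClasses.R
NULL

#' @importFrom stats shapiro.test oneway.test t.test ptukey quantile sd var
NULL

checkGroups <- function(groups, minN = 2L, needVar = TRUE) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a fully named list of numeric vectors")
  for (nm in names(groups)) {
    v <- groups[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("group '", nm, "' must contain finite numeric values")
    if (length(v) < minN)
      stop("group '", nm, "' has fewer than ", minN, " values")
    if (needVar && var(v) <= 0)
      stop("degenerate group '", nm, "': zero variance")
  }
  invisible(TRUE)
}

#' Shapiro-Wilk normality screen
#'
#' Normality screening of per-slice samples via the Shapiro-Wilk W test
#' (Royston's AS R94 approximation, as implemented in `stats::shapiro.test`).
#' The test is computed for any 3 <= n <= 5000 and reported together with an
#' advisory flag: the conventional screening regime applies it when the
#' slice count does not exceed 30, so `advisory` is `TRUE` there and the
#' result is informational beyond that size. The flag never changes what is
#' computed.
#'
#' @param values numeric sample.
#' @return one-row `data.frame` with `W`, `p.value`, `n` and `advisory`.
#' @examples
#' shapiroWilk(rnorm(20))
#' @export
shapiroWilk <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numbers")
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("sample size must satisfy 3 <= n <= 5000 (got ", n, ")")
  if (var(values) <= 0)
    stop("degenerate sample: zero variance")
  sw <- shapiro.test(values)
  data.frame(W = unname(sw$statistic), p.value = sw$p.value, n = n,
             advisory = n <= 30L)
}

#' Welch's one-way ANOVA
#'
#' Heteroscedasticity-robust one-way ANOVA (Welch 1951), the appropriate
#' omnibus test when group sizes and variances differ, as they do for
#' per-slice reduction ratios across prosthesis types with unequal slice
#' counts. Computed via `stats::oneway.test(var.equal = FALSE)`.
#'
#' @param groups named list of numeric vectors, one per group (k >= 2, each
#'   n >= 2 with positive variance).
#' @return one-row `data.frame` with `F`, `df1` (k - 1), `df2` (fractional
#'   Welch-adjusted denominator df) and `p.value`.
#' @examples
#' welchAnova(list(a = rnorm(10), b = rnorm(15, 1), c = rnorm(20, 0, 2)))
#' @export
welchAnova <- function(groups) {
  if (length(groups) < 2L) stop("Welch ANOVA needs at least 2 groups")
  checkGroups(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups))))
  res <- oneway.test(value ~ group, data = df, var.equal = FALSE)
  data.frame(F = unname(res$statistic),
             df1 = unname(res$parameter[1L]),
             df2 = unname(res$parameter[2L]),
             p.value = res$p.value)
}

#' Games-Howell post hoc test
#'
#' All pairwise comparisons after a Welch ANOVA, for unequal sizes and
#' variances: each pair gets a Welch-Satterthwaite df from
#' `s_a^2/n_a + s_b^2/n_b`, the statistic
#' `q = |mean_a - mean_b| / sqrt((s_a^2/n_a + s_b^2/n_b) / 2)`, and an
#' adjusted p-value from the studentized-range distribution with `k` means
#' and the pair's df (`stats::ptukey`).
#'
#' @param groups named list of numeric vectors (k >= 2, each n >= 2 with
#'   positive variance).
#' @param alpha two-sided significance level (default 0.05, i.e. a 95
#'   percent confidence level).
#' @return `data.frame` with one row per pair: `group_a`, `group_b`,
#'   `mean_diff` (a minus b), `se`, `q`, `df`, `p.adjusted`, `significant`.
#' @export
gamesHowell <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("Games-Howell needs at least 2 groups")
  checkGroups(groups)
  k <- length(groups)
  nms <- names(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(k, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se2 <- v[a] / n[a] + v[b] / n[b]
    dfp <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1L) +
                    (v[b] / n[b])^2 / (n[b] - 1L))
    q <- abs(m[a] - m[b]) / sqrt(se2 / 2)
    p <- ptukey(q, nmeans = k, df = dfp, lower.tail = FALSE)
    data.frame(group_a = nms[a], group_b = nms[b],
               mean_diff = unname(m[a] - m[b]), se = sqrt(se2 / 2),
               q = unname(q), df = unname(dfp), p.adjusted = unname(p),
               significant = unname(p < alpha))
  })
  do.call(rbind, out)
}

#' Welch two-sample t-test
#'
#' Two-sided independent-samples t-test; the Welch (unequal-variance) form
#' with Satterthwaite df is the default, consistent with the variance
#' heterogeneity that motivates the Welch ANOVA; `pooled = TRUE` gives the
#' classic Student form.
#'
#' @param a,b numeric samples (each n >= 2; at least one with positive
#'   variance).
#' @param pooled use the pooled-variance Student test instead of Welch.
#' @return one-row `data.frame` with `t`, `df`, `p.value` and `mean_diff`
#'   (a minus b).
#' @export
welchTTest <- function(a, b, pooled = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must contain finite values")
  if (var(a) <= 0 && var(b) <= 0)
    stop("degenerate samples: both variances are zero")
  res <- t.test(a, b, var.equal = pooled)
  data.frame(t = unname(res$statistic), df = unname(res$parameter),
             p.value = res$p.value, mean_diff = mean(a) - mean(b))
}

#' Factorial comparison of scan conditions
#'
#' Reproduces the 2x2 comparison structure over voxel size and tube
#' voltage: for each voxel size, the two tube voltages are compared, and for
#' each tube voltage, the two voxel sizes are compared, by independent
#' t-tests on per-slice MAR-off minus MAR-on differences.
#'
#' @param table `data.frame` with columns `voxel`, `kvp` and `value`
#'   (per-slice differences); exactly two levels of each factor, every cell
#'   with n >= 2.
#' @param alpha significance level.
#' @param pooled passed to [welchTTest()].
#' @return `data.frame` with four rows: `factor_tested`, `fixed_factor`,
#'   `fixed_level`, `level_a`, `level_b`, `t`, `df`, `p.value`,
#'   `significant`.
#' @export
compareConditions <- function(table, alpha = 0.05, pooled = FALSE) {
  need <- c("voxel", "kvp", "value")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table must be a data.frame with columns voxel, kvp, value")
  voxels <- sort(unique(table$voxel))
  kvps <- sort(unique(table$kvp))
  if (length(voxels) != 2L || length(kvps) != 2L)
    stop("incomplete design: need exactly two voxel and two kVp levels")
  cellOf <- function(vx, kv) table$value[table$voxel == vx & table$kvp == kv]
  for (vx in voxels) for (kv in kvps)
    if (length(cellOf(vx, kv)) < 2L)
      stop(sprintf("incomplete design: cell voxel=%s kvp=%s has n < 2",
                   format(vx), format(kv)))
  rows <- list()
  for (vx in voxels) {
    tt <- welchTTest(cellOf(vx, kvps[1L]), cellOf(vx, kvps[2L]),
                     pooled = pooled)
    rows[[length(rows) + 1L]] <- data.frame(
      factor_tested = "kvp", fixed_factor = "voxel",
      fixed_level = format(vx), level_a = format(kvps[1L]),
      level_b = format(kvps[2L]), t = tt$t, df = tt$df,
      p.value = tt$p.value, significant = tt$p.value < alpha)
  }
  for (kv in kvps) {
    tt <- welchTTest(cellOf(voxels[1L], kv), cellOf(voxels[2L], kv),
                     pooled = pooled)
    rows[[length(rows) + 1L]] <- data.frame(
      factor_tested = "voxel", fixed_factor = "kvp",
      fixed_level = format(kv), level_a = format(voxels[1L]),
      level_b = format(voxels[2L]), t = tt$t, df = tt$df,
      p.value = tt$p.value, significant = tt$p.value < alpha)
  }
  do.call(rbind, rows)
}
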