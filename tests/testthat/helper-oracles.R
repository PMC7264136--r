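# Independent brute-force oracles. Everything here recomputes the pipeline
# stages from their definitions (per-pixel loops, dense convolution,
# breadth-first floods, direct formula transcription) without touching the
# package's compiled code paths.

# symmetric half-sample reflection of index i into 1..n
oracleRefl <- function(i, n) {
  if (n == 1L) return(1L)
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracleMedian3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    w <- numeric(9); k <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      k <- k + 1L
      w[k] <- x[oracleRefl(r + dr, nr), oracleRefl(c + dc, nc)]
    }
    out[r, c] <- sort(w)[5L]
  }
  out
}

# dense 2-D convolution with an outer-product kernel, reflected borders
oracleConv2 <- function(x, k1d) {
  nr <- nrow(x); nc <- ncol(x)
  rad <- (length(k1d) - 1L) / 2L
  kern <- outer(k1d, k1d)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s <- 0
    for (dr in -rad:rad) for (dc in -rad:rad)
      s <- s + kern[dr + rad + 1L, dc + rad + 1L] *
        x[oracleRefl(r + dr, nr), oracleRefl(c + dc, nc)]
    out[r, c] <- s
  }
  out
}

oracleSobel <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)   # [dr, dc] col weights
  ky <- t(kx)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    sx <- 0; sy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- x[oracleRefl(r + dr, nr), oracleRefl(c + dc, nc)]
      sx <- sx + kx[dr + 2L, dc + 2L] * v
      sy <- sy + ky[dr + 2L, dc + 2L] * v
    }
    gx[r, c] <- sx; gy[r, c] <- sy
  }
  list(gx = gx, gy = gy,
       magnitude = sqrt(gx^2 + gy^2), direction = atan2(gy, gx))
}

# sector table: boundaries at odd multiples of 22.5 degrees
oracleSector <- function(theta) {
  a <- theta %% pi
  deg <- a * 180 / pi
  if (deg < 22.5 || deg >= 157.5) 0L
  else if (deg < 67.5) 1L
  else if (deg < 112.5) 2L
  else 3L
}

oracleNms <- function(mag, dir) {
  nr <- nrow(mag); nc <- ncol(mag)
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s <- oracleSector(dir[r, c])
    d <- off[[s + 1L]]
    keep <- TRUE
    for (sgn in c(1L, -1L)) {
      r2 <- r + sgn * d[1L]; c2 <- c + sgn * d[2L]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
          mag[r, c] < mag[r2, c2]) keep <- FALSE
    }
    out[r, c] <- if (keep) mag[r, c] else 0
  }
  out
}

oracleDR <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
oracleDC <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)

# breadth-first flood from strong pixels through weak/strong chains
oracleHysteresis <- function(mag, low, high) {
  nr <- nrow(mag); nc <- ncol(mag)
  out <- matrix(FALSE, nr, nc)
  queue <- which(mag >= high)
  out[queue] <- TRUE
  head <- 1L
  while (head <= length(queue)) {
    idx <- queue[head]; head <- head + 1L
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    for (j in 1:8) {
      r2 <- r + oracleDR[j]; c2 <- c + oracleDC[j]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      i2 <- r2 + (c2 - 1L) * nr
      if (!out[i2] && mag[i2] >= low) {
        out[i2] <- TRUE
        queue <- c(queue, i2)
      }
    }
  }
  out
}

# flood-fill component count
oracleCount <- function(px, conn = 8L) {
  nr <- nrow(px); nc <- ncol(px)
  nn <- if (conn == 8L) 8L else 4L
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (start in which(px)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      idx <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
      for (j in seq_len(nn)) {
        r2 <- r + oracleDR[j]; c2 <- c + oracleDC[j]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        i2 <- r2 + (c2 - 1L) * nr
        if (px[i2] && !seen[i2]) {
          seen[i2] <- TRUE
          stack <- c(stack, i2)
        }
      }
    }
  }
  count
}

# quantile with h = n*p linear interpolation (transcribed definition)
oracleQuantile4 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- n * p
  if (h < 1) return(x[1L])
  k <- floor(h)
  if (k >= n) return(x[n])
  x[k] + (h - k) * (x[k + 1L] - x[k])
}

# Welch one-way ANOVA by direct transcription of the 1951 formulas
oracleWelchAnova <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, function(g) sum((g - mean(g))^2) / (length(g) - 1),
              numeric(1))
  w <- n / v
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  B <- sum((1 - w / W)^2 / (n - 1))
  Fstat <- A / (1 + 2 * (k - 2) / (k^2 - 1) * B)
  df2 <- (k^2 - 1) / (3 * B)
  list(F = Fstat, df1 = k - 1, df2 = df2,
       p = stats::pf(Fstat, k - 1, df2, lower.tail = FALSE))
}

# Welch t by direct transcription
oracleWelchT <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# studentized-range CDF by numerical quadrature: outer integral over the
# scale factor s = sqrt(chisq_df / df), inner integral over the smallest
# of the k normal deviates
oracleSRcdf <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z)
      k * stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  fs <- function(s)
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  stats::integrate(function(s) vapply(s, function(si) fs(si) * inner(si),
                                      numeric(1)),
                   0, Inf, rel.tol = 1e-8)$value
}

oracleGamesHowellP <- function(a, b, k) {
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / length(a) + vb / length(b)
  q <- abs(mean(a) - mean(b)) / sqrt(se2 / 2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  1 - oracleSRcdf(q, k, df)
}
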