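# Independent naive implementations used as oracles; deliberately written
# from the definitions, not shared with the package internals.

oracle_first_order <- function(x, bins = 64L) {
  n <- length(x)
  mu <- sum(x) / n
  cm <- function(k) sum((x - mu)^k) / n
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  lo <- xs[1]; hi <- xs[n]
  if (hi > lo) {
    cnt <- integer(bins)
    for (v in x) {
      b <- 1L + floor((v - lo) / (hi - lo) * bins)
      if (b > bins) b <- bins
      cnt[b] <- cnt[b] + 1L
    }
    p <- cnt[cnt > 0] / n
  } else {
    p <- 1
  }
  c(energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    kurtosis = cm(4) / cm(2)^2,
    maximum = hi,
    mean = mu,
    mean_absolute_deviation = sum(abs(x - mu)) / n,
    median = med,
    minimum = lo,
    range = hi - lo,
    rms = sqrt(sum(x^2) / n),
    skewness = cm(3) / cm(2)^1.5,
    standard_deviation = sqrt(cm(2)),
    uniformity = sum(p^2),
    variance = cm(2))
}

# exhaustive minimum-within-cluster-variance partition of a 1-D sample into
# k contiguous (in sorted order) clusters; returns the optimal total
# within-cluster sum of squares
oracle_kmeans_wss <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    b <- c(0, splits[, j], n)
    w <- 0
    for (m in seq_len(k)) {
      seg <- xs[(b[m] + 1):b[m + 1]]
      w <- w + sum((seg - mean(seg))^2)
    }
    if (w < best) best <- w
  }
  best
}

# brute-force 3-D convolution of a digital sphere with a Gaussian kernel,
# returning the mean recovered value inside the true sphere
oracle_sphere_rc <- function(d_mm, fwhm_mm, h = 0.5) {
  R <- d_mm / 2
  sg <- fwhm_mm / (2 * sqrt(2 * log(2)))
  g <- seq(-(R + 4 * sg), R + 4 * sg, by = h)
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  sph <- d2 <= R^2
  k1 <- dnorm(g / sg)
  k1 <- k1 / sum(k1)
  n <- length(g)
  smooth_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (j in seq_len(n)) {
      s <- seq_len(n) + (j - (n + 1) / 2)
      ok <- s >= 1 & s <= n
      if (!any(ok)) next
      w <- k1[j]
      if (axis == 1) out[which(ok), , ] <- out[which(ok), , ] + w * a[s[ok], , ]
      else if (axis == 2) out[, which(ok), ] <- out[, which(ok), ] + w * a[, s[ok], ]
      else out[, , which(ok)] <- out[, , which(ok)] + w * a[, , s[ok]]
    }
    out
  }
  b <- sph * 1.0
  for (ax in 1:3) b <- smooth_axis(b, ax)
  mean(b[sph])
}
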