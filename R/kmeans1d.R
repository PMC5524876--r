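#' One-dimensional k-means intensity clustering
#'
#' Partitions a sample of scalar intensities into `k` clusters minimising the
#' within-cluster sum of squares, and reports the decision boundaries
#' ("cut-off points") between adjacent clusters. This is the primitive behind
#' every classification step of the semi-automated lesion segmentation: the
#' two-compartment split of DCE subtraction intensities and the
#' three-compartment splits of DWI b0 and ADC intensities.
#'
#' Because the data are one-dimensional, the globally optimal partition is
#' computable: clusters in an optimal solution are contiguous in sorted order,
#' so for samples up to `exact_n` points an exact dynamic program over the
#' sorted values is used (deterministic, independent of `seed`). Larger
#' samples fall back to Lloyd iterations with deterministic quantile seeding
#' (centroid i at quantile (2i-1)/(2k)) and seeded random restarts if a
#' cluster empties. Clusters are always reported in ascending centroid order;
#' cut-offs are the midpoints of adjacent centroids, i.e. the nearest-centroid
#' decision boundaries.
#'
#' @param values numeric vector of intensities (NA dropped).
#' @param k number of clusters (>= 1).
#' @param seed integer; only consulted by the random-restart fallback of the
#'   large-sample Lloyd branch.
#' @param tol Lloyd convergence tolerance on the maximum centroid shift.
#' @param max_iter Lloyd iteration cap.
#' @param exact_n sample-size threshold below which the exact dynamic program
#'   is used.
#' @return An object of class `kmeans1d`: list with `centroids` (ascending),
#'   `cutoffs` (length k-1 midpoints), `labels` (cluster index per input
#'   value, 1 = lowest), `sizes`, `withinss` (total within-cluster SS) and
#'   `method` ("dp" or "lloyd").
#' @examples
#' km <- kmeans_1d(c(0, 0, 0, 10, 10, 10), k = 2)
#' km$centroids  # 0 and 10
#' km$cutoffs    # 5
#' @export
kmeans_1d <- function(values, k, seed = 1L, tol = 1e-8, max_iter = 200L,
                      exact_n = 2048L) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  n <- length(x)
  k <- as.integer(k)
  if (k < 1L) stop_lq("lq_argument_error", "k must be >= 1")
  nuniq <- length(unique(x))
  if (nuniq < k)
    stop_lq("lq_degenerate_error",
            "fewer than k = %d distinct values (%d) for 1-D k-means", k, nuniq)
  if (n <= exact_n) {
    fit <- kmeans_1d_dp(x, k)
  } else {
    fit <- kmeans_1d_lloyd(x, k, seed = seed, tol = tol, max_iter = max_iter)
  }
  cen <- fit$centroids
  cutoffs <- if (k > 1) (cen[-k] + cen[-1]) / 2 else numeric(0)
  labels <- if (k > 1) findInterval(x, cutoffs) + 1L else rep(1L, n)
  out <- rep(NA_integer_, length(values))
  out[!is.na(values)] <- labels
  structure(list(centroids = cen, cutoffs = cutoffs, labels = out,
                 sizes = tabulate(labels, k), withinss = fit$withinss,
                 method = fit$method),
            class = "kmeans1d")
}

#' @export
print.kmeans1d <- function(x, ...) {
  cat(sprintf("<kmeans1d> k = %d (%s)\n", length(x$centroids), x$method))
  cat("  centroids:", paste(signif(x$centroids, 6), collapse = ", "), "\n")
  if (length(x$cutoffs))
    cat("  cutoffs:  ", paste(signif(x$cutoffs, 6), collapse = ", "), "\n")
  invisible(x)
}

# exact optimal 1-D k-means by dynamic programming over sorted values.
# cost(j, i): within-SS of x_sorted[j..i], from prefix sums.
kmeans_1d_dp <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  s1 <- c(0, cumsum(xs))
  s2 <- c(0, cumsum(xs^2))
  cost_to <- function(j, i) {
    # vectorised over j
    m <- i - j + 1
    (s2[i + 1] - s2[j]) - (s1[i + 1] - s1[j])^2 / m
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- cost_to(1L, seq_len(n))
  if (k > 1) {
    for (m in 2:k) {
      for (i in m:n) {
        j <- m:i
        tot <- D[m - 1, j - 1] + cost_to(j, i)
        b <- which.min(tot)
        D[m, i] <- tot[b]
        B[m, i] <- j[b]
      }
    }
  }
  # backtrack segment start indices; segment m spans starts[m]..ends[m]
  starts <- integer(k)
  ends <- integer(k)
  i <- n
  for (m in k:1) {
    starts[m] <- if (m == 1) 1L else B[m, i]
    ends[m] <- i
    i <- starts[m] - 1L
  }
  centroids <- vapply(seq_len(k), function(m) {
    mean(xs[starts[m]:ends[m]])
  }, numeric(1))
  # segments ascend, so centroids already sorted
  list(centroids = centroids, withinss = D[k, n], method = "dp")
}

kmeans_1d_lloyd <- function(x, k, seed, tol, max_iter) {
  run <- function(cen) {
    cen <- sort(cen)
    for (it in seq_len(max_iter)) {
      cuts <- (cen[-k] + cen[-1]) / 2
      lab <- findInterval(x, cuts) + 1L
      ns <- tabulate(lab, k)
      if (any(ns == 0L)) return(NULL)
      new_cen <- vapply(seq_len(k), function(m) mean(x[lab == m]), numeric(1))
      shift <- max(abs(new_cen - cen))
      cen <- sort(new_cen)
      if (shift < tol) break
    }
    cuts <- (cen[-k] + cen[-1]) / 2
    lab <- findInterval(x, cuts) + 1L
    wss <- sum((x - cen[lab])^2)
    list(centroids = cen, withinss = wss, method = "lloyd")
  }
  init <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                          names = FALSE, type = 7)
  fit <- if (anyDuplicated(init)) NULL else run(init)
  if (is.null(fit)) {
    # seeded multi-restart from random distinct values
    ux <- unique(x)
    for (try in 1:20) {
      cen0 <- with_local_seed(seed + try, sample(ux, k))
      fit <- run(cen0)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop_lq("lq_degenerate_error", "1-D k-means failed to find %d non-empty clusters", k)
  }
  fit
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
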