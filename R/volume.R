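#' 3-D image volume
#'
#' The universal carrier for DCE, DWI, ADC and PET data: a 3-D numeric array
#' plus its voxel spacing (mm) and the world coordinate (mm) of the centre of
#' voxel `[1, 1, 1]`. All indices in this package are 1-based and inclusive;
#' world coordinates refer to voxel centres.
#'
#' @param data numeric 3-D array of voxel values.
#' @param spacing numeric length-3, per-axis voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @return An object of class `image_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), spacing = c(1.4, 1.4, 3))
#' voxel_volume_mm3(v)
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_lq("lq_argument_error", "'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_lq("lq_argument_error", "'spacing' must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_lq("lq_argument_error", "'origin' must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%s) mm\n",
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Binary segmentation mask on an image grid
#'
#' @param mask logical 3-D array (TRUE = inside).
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `seg_mask`.
#' @seealso [mask_volume_cc()]
#' @export
seg_mask <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (is.numeric(mask)) mask <- array(mask != 0, dim = dim(mask))
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop_lq("lq_argument_error", "'mask' must be a logical 3-D array")
  mask[is.na(mask)] <- FALSE
  v <- image_volume(array(0, dim(mask)), spacing, origin)
  structure(list(mask = mask, spacing = v$spacing, origin = v$origin),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels inside (%.3f cc) on %s grid\n",
              format(sum(x$mask)), mask_volume_cc(x),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Mask volume in cc
#'
#' Voxel count times voxel volume, converted from mm^3 to cc.
#' @param mask a `seg_mask`.
#' @return Volume in cc (cm^3).
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sum(mask$mask) * prod(mask$spacing) / 1000
}

#' Voxel volume in mm^3
#' @param x an `image_volume` or `seg_mask`.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(grid_data(a)), dim(grid_data(b))) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

grid_data <- function(x) if (inherits(x, "seg_mask")) x$mask else x$data

# world coordinates of voxel centres along one axis
axis_centers <- function(x, axis) {
  n <- dim(grid_data(x))[axis]
  x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]
}

#' A 3-D index box
#'
#' Inclusive 1-based index ranges selecting a rectangular region of a grid,
#' the in-silico counterpart of the operator-drawn rectangular box around the
#' lesion.
#'
#' @param lo,hi integer length-3 lower/upper corner indices (inclusive).
#' @return Object of class `index_box`.
#' @export
index_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(is.na(lo)) || any(is.na(hi)))
    stop_lq("lq_argument_error", "box corners must be 3 integers each")
  if (any(lo < 1L) || any(hi < lo))
    stop_lq("lq_argument_error", "box must satisfy 1 <= lo <= hi")
  structure(list(lo = lo, hi = hi), class = "index_box")
}

box_mask <- function(box, x) {
  d <- dim(grid_data(x))
  if (any(box$hi > d))
    stop_lq("lq_argument_error", "box exceeds grid extent %s",
            paste(d, collapse = "x"))
  m <- array(FALSE, d)
  m[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- TRUE
  m
}

#' Resample a mask onto another grid (nearest neighbour)
#'
#' Maps each target voxel centre into the source grid's world frame; the
#' target voxel is inside the resampled mask iff its centre falls inside the
#' source mask (nearest source voxel is TRUE). Used to carry the DCE
#' enhanced-tissue mask onto the DWI grid in place of scanner co-registration.
#'
#' @param mask a `seg_mask` on the source grid.
#' @param template an `image_volume` or `seg_mask` defining the target grid.
#' @return A `seg_mask` on the target grid.
#' @export
resample_mask_to_grid <- function(mask, template) {
  stopifnot(inherits(mask, "seg_mask"))
  d_src <- dim(mask$mask)
  idx <- lapply(1:3, function(a) {
    w <- axis_centers(template, a)
    j <- as.integer(round((w - mask$origin[a]) / mask$spacing[a])) + 1L
    j[j < 1L | j > d_src[a]] <- NA_integer_
    j
  })
  if (all(is.na(idx[[1]])) || all(is.na(idx[[2]])) || all(is.na(idx[[3]])))
    stop_lq("lq_geometry_error",
            "target grid has no spatial overlap with the source mask")
  out <- mask$mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out[is.na(out)] <- FALSE
  seg_mask(out, template$spacing, template$origin)
}

#' Label connected components of a binary mask
#'
#' 26-connectivity by default, via the voxel-adjacency graph.
#'
#' @param mask logical 3-D array or `seg_mask`.
#' @param connectivity 6 or 26.
#' @return Integer array of the same shape; 0 outside, component label inside.
#' @export
label_components <- function(mask, connectivity = 26) {
  m <- if (inherits(mask, "seg_mask")) mask$mask else mask
  d <- dim(m)
  lab <- array(0L, d)
  idx <- which(m)
  if (length(idx) == 0L) return(lab)
  co <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  # keep one of each +/- pair
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
          (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[keep, , drop = FALSE]
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    j <- match(nb_lin, idx)
    hit <- !is.na(j)
    if (any(hit))
      edges <- c(edges, rbind(which(ok)[hit], j[hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# separable Gaussian smoothing in voxel units; zero-padded boundaries
gaussian_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  d <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (j in -r:r) {
      src <- seq_len(n) + j
      ok <- src >= 1L & src <= n
      if (!any(ok)) next
      dst <- which(ok)
      s <- src[ok]
      wt <- w[j + r + 1L]
      if (axis == 1) out[dst, , ] <- out[dst, , ] + wt * arr[s, , ]
      else if (axis == 2) out[, dst, ] <- out[, dst, ] + wt * arr[, s, ]
      else out[, , dst] <- out[, , dst] + wt * arr[, , s]
    }
    arr <- out
  }
  arr
}
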