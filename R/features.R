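FIRST_ORDER_NAMES <- c(
  "energy", "entropy", "kurtosis", "maximum", "mean",
  "mean_absolute_deviation", "median", "minimum", "range", "rms",
  "skewness", "standard_deviation", "uniformity", "variance"
)

SHAPE_NAMES <- c("surface_area_cm2", "spherical_disproportion", "sphericity",
                 "surface_to_volume_cm_inv")

PET_MACRO_NAMES <- c("mtv_cc", "suv_mean_pvc", "suv_max", "tlg_g")
MR_MACRO_NAMES <- c("v_adc_cc", "adc_mean", "adc_min", "tld_cm5_s")

#' Canonical feature names for one modality
#'
#' The frozen 22-name schema: 4 macroscopic + 14 first-order + 4 shape/size
#' features per modality.
#'
#' @param modality `"PET"` or `"MR"`.
#' @return Character vector of 22 names.
#' @export
feature_names <- function(modality = c("PET", "MR")) {
  modality <- match.arg(modality)
  macro <- if (modality == "PET") PET_MACRO_NAMES else MR_MACRO_NAMES
  c(macro, FIRST_ORDER_NAMES, SHAPE_NAMES)
}

#' First-order histogram features of an intensity sample
#'
#' The 14 first-order statistics of the voxel intensities within a mask.
#' Definitions (N values \eqn{x_i}, population moments \eqn{m_j} about the
#' mean):
#' energy \eqn{\sum x_i^2}; rms \eqn{\sqrt{\sum x_i^2 / N}};
#' variance \eqn{m_2} (population), standard deviation \eqn{\sqrt{m_2}};
#' mean absolute deviation \eqn{\frac1N\sum |x_i - \bar x|};
#' skewness \eqn{m_3 / m_2^{3/2}} and kurtosis \eqn{m_4 / m_2^2} (population
#' moment ratios, kurtosis not excess-corrected);
#' entropy \eqn{-\sum_b p_b \log_2 p_b} and uniformity \eqn{\sum_b p_b^2}
#' over a fixed-bin histogram between the in-mask minimum and maximum (empty
#' bins contribute 0).
#'
#' A constant sample yields entropy 0, uniformity 1 and all dispersion
#' features 0, with skewness and kurtosis undefined (`NA`).
#'
#' @param values numeric vector of in-mask intensities (NA dropped; at least
#'   one value).
#' @param bins histogram bin count for entropy/uniformity (default 64).
#' @return Named numeric vector of the 14 features.
#' @examples
#' first_order_features(c(1, 2, 3))[c("mean", "energy", "variance")]
#' @export
first_order_features <- function(values, bins = 64L) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop_lq("lq_argument_error", "empty intensity sample")
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    breaks <- seq(lo, hi, length.out = bins + 1L)
    bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    p <- tabulate(bin, bins) / n
  } else {
    p <- 1
  }
  p <- p[p > 0]
  c(energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    maximum = hi,
    mean = mu,
    mean_absolute_deviation = sum(abs(x - mu)) / n,
    median = stats::median(x),
    minimum = lo,
    range = hi - lo,
    rms = sqrt(sum(x^2) / n),
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    standard_deviation = sqrt(m2),
    uniformity = sum(p^2),
    variance = m2)
}

#' Shape and size features of a segmentation mask
#'
#' Volume V comes from the voxel count (cc); surface area A from a
#' triangulated 0.5-level isosurface of the (optionally anti-aliased) mask,
#' extracted by marching tetrahedra (cm^2). From these:
#' sphericity \eqn{\pi^{1/3} (6V)^{2/3} / A}, spherical disproportion
#' \eqn{A / (4\pi R^2)} with \eqn{R = (3V/4\pi)^{1/3}} (the two are exact
#' reciprocals), and surface-to-volume ratio \eqn{A/V} (cm^-1).
#'
#' `surface_mode = "mesh"` (default) pre-smooths the binary mask with a
#' Gaussian of `smooth_sigma` voxels before meshing; without this
#' anti-aliasing step the staircase surface of a digital sphere overestimates
#' the analytic area by roughly 9%. `surface_mode = "faces"` counts exposed
#' voxel faces instead (exact for axis-aligned blocks such as cubes, strongly
#' biased for curved shapes).
#'
#' @param mask a `seg_mask` (non-empty).
#' @param surface_mode `"mesh"` or `"faces"`.
#' @param smooth_sigma anti-alias smoothing in voxels for mesh mode
#'   (default 0.7; 0 disables).
#' @return Named numeric vector of the 4 shape features.
#' @export
shape_features <- function(mask, surface_mode = c("mesh", "faces"),
                           smooth_sigma = 0.7) {
  stopifnot(inherits(mask, "seg_mask"))
  surface_mode <- match.arg(surface_mode)
  if (!any(mask$mask)) stop_lq("lq_argument_error", "empty mask")
  v_cc <- mask_volume_cc(mask)
  a_cm2 <- surface_area_cm2(mask, mode = surface_mode,
                            smooth_sigma = smooth_sigma)
  r_cm <- (3 * v_cc / (4 * pi))^(1 / 3)
  c(surface_area_cm2 = a_cm2,
    spherical_disproportion = a_cm2 / (4 * pi * r_cm^2),
    sphericity = pi^(1 / 3) * (6 * v_cc)^(2 / 3) / a_cm2,
    surface_to_volume_cm_inv = a_cm2 / v_cc)
}

#' Surface area of a mask (cm^2)
#'
#' @inheritParams shape_features
#' @param mode `"mesh"` (triangulated isosurface) or `"faces"` (exposed voxel
#'   faces).
#' @return Surface area in cm^2.
#' @export
surface_area_cm2 <- function(mask, mode = c("mesh", "faces"),
                             smooth_sigma = 0.7) {
  stopifnot(inherits(mask, "seg_mask"))
  mode <- match.arg(mode)
  if (mode == "faces") return(face_area_mm2(mask$mask, mask$spacing) / 100)
  pad <- max(2L, as.integer(ceiling(3 * smooth_sigma)) + 1L)
  f0 <- pad_array(mask$mask * 1.0, pad)
  f <- if (smooth_sigma > 0) gaussian_smooth_3d(f0, smooth_sigma) else f0
  # structures thinner than the anti-alias kernel melt below the iso-level;
  # fall back to the raw binary surface when most of the mask would vanish
  if (mean(f[f0 > 0] > 0.5) < 0.5) f <- f0
  marching_tetrahedra_area_mm2(f, mask$spacing, level = 0.5) / 100
}

pad_array <- function(arr, p) {
  d <- dim(arr)
  out <- array(0, d + 2L * p)
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- arr
  out
}

face_area_mm2 <- function(m, spacing) {
  d <- dim(m)
  p <- array(FALSE, d + 2L)
  p[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
  dp <- dim(p)
  nfx <- sum(p[-1, , ] != p[-dp[1], , ])
  nfy <- sum(p[, -1, ] != p[, -dp[2], ])
  nfz <- sum(p[, , -1] != p[, , -dp[3]])
  nfx * spacing[2] * spacing[3] + nfy * spacing[1] * spacing[3] +
    nfz * spacing[1] * spacing[2]
}

# Triangulated isosurface area by marching tetrahedra: each grid cell is
# split into 6 tetrahedra around the main diagonal; within a tetrahedron the
# level surface is a triangle or a quad with vertices linearly interpolated
# on the edges. Only the total area is needed, so no topology is kept.
marching_tetrahedra_area_mm2 <- function(f, spacing, level = 0.5) {
  d <- dim(f)
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  V <- vector("list", 8L)
  for (cc in 1:8)
    V[[cc]] <- as.vector(f[off[cc, 1] + seq_len(nx),
                           off[cc, 2] + seq_len(ny),
                           off[cc, 3] + seq_len(nz)])
  minv <- do.call(pmin, V)
  maxv <- do.call(pmax, V)
  active <- which(maxv > level & minv <= level)
  if (length(active) == 0L) return(0)
  for (cc in 1:8) V[[cc]] <- V[[cc]][active]
  # cell base coordinates (mm) of active cells
  ai <- arrayInd(active, c(nx, ny, nz))
  base <- cbind((ai[, 1] - 1) * spacing[1],
                (ai[, 2] - 1) * spacing[2],
                (ai[, 3] - 1) * spacing[3])
  corner_xyz <- lapply(1:8, function(cc)
    sweep(base, 2, off[cc, ] * spacing, "+"))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  interp <- function(ia, ib, vals, pts, rows) {
    va <- vals[[ia]][rows]; vb <- vals[[ib]][rows]
    tt <- (level - va) / (vb - va)
    pts[[ia]][rows, , drop = FALSE] +
      tt * (pts[[ib]][rows, , drop = FALSE] - pts[[ia]][rows, , drop = FALSE])
  }
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  total <- 0
  for (t in seq_len(nrow(tets))) {
    ids <- tets[t, ]
    above <- cbind(V[[ids[1]]] > level, V[[ids[2]]] > level,
                   V[[ids[3]]] > level, V[[ids[4]]] > level)
    nab <- rowSums(above)
    # one vertex isolated (1 above or 3 above): single triangle
    for (cnt in c(1L, 3L)) {
      rows <- which(nab == cnt)
      if (!length(rows)) next
      lone_col <- if (cnt == 1L) max.col(above[rows, , drop = FALSE])
                  else max.col(!above[rows, , drop = FALSE])
      for (lc in 1:4) {
        rr <- rows[lone_col == lc]
        if (!length(rr)) next
        others <- setdiff(1:4, lc)
        p1 <- interp(ids[lc], ids[others[1]], V, corner_xyz, rr)
        p2 <- interp(ids[lc], ids[others[2]], V, corner_xyz, rr)
        p3 <- interp(ids[lc], ids[others[3]], V, corner_xyz, rr)
        total <- total + sum(tri_area(p1, p2, p3))
      }
    }
    # two above / two below: quad split into two triangles
    rows2 <- which(nab == 2L)
    if (length(rows2)) {
      pairs <- utils::combn(1:4, 2)
      for (pc in seq_len(ncol(pairs))) {
        i1 <- pairs[1, pc]; i2 <- pairs[2, pc]
        rr <- rows2[above[rows2, i1] & above[rows2, i2]]
        if (!length(rr)) next
        outs <- setdiff(1:4, c(i1, i2))
        e11 <- interp(ids[i1], ids[outs[1]], V, corner_xyz, rr)
        e12 <- interp(ids[i1], ids[outs[2]], V, corner_xyz, rr)
        e21 <- interp(ids[i2], ids[outs[1]], V, corner_xyz, rr)
        e22 <- interp(ids[i2], ids[outs[2]], V, corner_xyz, rr)
        total <- total + sum(tri_area(e11, e12, e22)) +
          sum(tri_area(e11, e22, e21))
      }
    }
  }
  total
}

#' Total lesion diffusion (TLD)
#'
#' The MR analogue of TLG: the product of the mean ADC within the functional
#' volume and the functional volume itself, expressed in cm^5/s. With ADC on
#' the printed clinical scale (units written mm^2/s) and V_ADC in cc, the
#' unit algebra mm^2 * cm^3 = 10^-2 cm^5 gives
#' `TLD = ADC_mean * V_ADC * 1e-2`.
#'
#' @param adc_mean mean ADC within V_ADC (printed mm^2/s scale), >= 0.
#' @param v_adc_cc functional volume (cc), >= 0.
#' @param unit_factor unit conversion factor (default 1e-2, mm^2 cm^3 ->
#'   cm^5).
#' @return TLD in cm^5/s.
#' @examples
#' compute_tld(1000, 10)  # 100 cm^5/s
#' @export
compute_tld <- function(adc_mean, v_adc_cc, unit_factor = 1e-2) {
  if (adc_mean < 0 || v_adc_cc < 0)
    stop_lq("lq_argument_error", "TLD inputs must be non-negative")
  as.numeric(adc_mean) * as.numeric(v_adc_cc) * unit_factor
}

#' Assemble the 22-feature vector of one modality
#'
#' Validates the frozen schema (4 macroscopic + 14 first-order + 4
#' shape/size, names bijective with [feature_names()]) and returns a single
#' named vector serialisable to one CSV row.
#'
#' @param macroscopic named numeric length 4 (`mtv_cc`, `suv_mean_pvc`,
#'   `suv_max`, `tlg_g` for PET; `v_adc_cc`, `adc_mean`, `adc_min`,
#'   `tld_cm5_s` for MR).
#' @param first_order named numeric length 14, as from
#'   [first_order_features()].
#' @param shape named numeric length 4, as from [shape_features()].
#' @param modality `"PET"` or `"MR"`.
#' @return Object of class `feature_vector`: named numeric length 22 with
#'   attribute `modality`.
#' @export
assemble_feature_vector <- function(macroscopic, first_order, shape,
                                    modality = c("PET", "MR")) {
  modality <- match.arg(modality)
  want <- feature_names(modality)
  got <- c(macroscopic, first_order, shape)
  if (anyDuplicated(names(got)))
    stop_lq("lq_schema_error", "duplicate feature name: %s",
            paste(names(got)[duplicated(names(got))], collapse = ", "))
  if (length(got) != 22L || !setequal(names(got), want)) {
    missing <- setdiff(want, names(got))
    extra <- setdiff(names(got), want)
    stop_lq("lq_schema_error",
            "feature schema violation (missing: %s; extra: %s)",
            paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  structure(got[want], modality = modality, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s, %d features\n", attr(x, "modality"),
              length(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  pre <- tolower(attr(x, "modality"))
  df <- as.data.frame(as.list(unclass(x)))
  names(df) <- paste(pre, names(x), sep = "_")
  df
}

#' Extract the full 22-feature vector from a segmented volume
#'
#' Convenience wrapper: computes first-order features on the in-mask voxel
#' values and shape features on the mask, and joins them with the supplied
#' macroscopic features.
#'
#' @param volume `image_volume` (SUV or ADC map).
#' @param mask `seg_mask` on the same grid (MTV or V_ADC).
#' @param macroscopic named numeric length 4 (see
#'   [assemble_feature_vector()]).
#' @param modality `"PET"` or `"MR"`.
#' @param bins histogram bins for entropy/uniformity.
#' @param surface_mode,smooth_sigma passed to [shape_features()].
#' @return A `feature_vector`.
#' @export
extract_features <- function(volume, mask, macroscopic,
                             modality = c("PET", "MR"), bins = 64L,
                             surface_mode = "mesh", smooth_sigma = 0.7) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "seg_mask"))
  if (!same_grid(volume, mask))
    stop_lq("lq_geometry_error", "mask grid does not match the volume grid")
  fo <- first_order_features(volume$data[mask$mask], bins = bins)
  sh <- shape_features(mask, surface_mode = surface_mode,
                       smooth_sigma = smooth_sigma)
  assemble_feature_vector(macroscopic, fo, sh, modality = modality)
}
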