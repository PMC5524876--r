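#' Pair of DWI volumes at two b-values
#'
#' @param s_low `image_volume`, signal at the lower b-value (typically b = 0).
#' @param s_high `image_volume`, signal at the higher b-value (typically
#'   b = 900 s/mm^2).
#' @param b_low,b_high diffusion weightings in s/mm^2, `b_high > b_low >= 0`.
#' @return Object of class `dwi_pair`.
#' @export
dwi_pair <- function(s_low, s_high, b_low = 0, b_high = 900) {
  stopifnot(inherits(s_low, "image_volume"), inherits(s_high, "image_volume"))
  if (!same_grid(s_low, s_high))
    stop_lq("lq_geometry_error", "DWI volumes must share grid, spacing and origin")
  if (!(b_high > b_low && b_low >= 0))
    stop_lq("lq_argument_error", "need b_high > b_low >= 0 (got %g, %g)",
            b_low, b_high)
  structure(list(s_low = s_low, s_high = s_high,
                 b_low = as.numeric(b_low), b_high = as.numeric(b_high)),
            class = "dwi_pair")
}

#' Compute an ADC map from a two-point DWI acquisition
#'
#' Voxelwise apparent diffusion coefficient from the logarithm of the signal
#' ratio between the two b-values:
#' \deqn{ADC = \frac{\ln(S_{low}/S_{high})}{b_{high} - b_{low}}}
#' Voxels where either signal is non-positive (or below `noise_floor`) cannot
#' support the log-ratio and are marked invalid (`NA` in the map, `FALSE` in
#' the accompanying validity mask) rather than clamped, so that histogram
#' features downstream are not silently biased. Negative computed ADC values
#' (possible when noise makes `s_high > s_low`) are retained unless
#' `floor_zero = TRUE`.
#'
#' ADC maps in this package are carried in the printed clinical convention:
#' magnitudes of order 10^3 in units written "mm^2/s", physically
#' 10^-6 mm^2/s. `scale` (default `1e6`) converts the raw log-ratio estimate
#' (mm^2/s) onto that scale; set `scale = 1` for physical units.
#'
#' @param pair a [dwi_pair()].
#' @param mask optional `seg_mask`; voxels outside are invalid in the output.
#' @param scale multiplicative output scale (default 1e6, printed convention).
#' @param noise_floor signals at or below this value are invalid (default 0).
#' @param floor_zero clip negative ADC estimates to zero.
#' @return An `image_volume` (ADC) with attribute `valid`, a `seg_mask` of
#'   voxels where the estimate is defined.
#' @examples
#' b0 <- image_volume(array(exp(1), c(4, 4, 4)), c(1, 1, 1))
#' b9 <- image_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
#' adc <- compute_adc_map(dwi_pair(b0, b9), scale = 1)
#' adc$data[1, 1, 1] * 900  # = 1
#' @export
compute_adc_map <- function(pair, mask = NULL, scale = 1e6, noise_floor = 0,
                            floor_zero = FALSE) {
  stopifnot(inherits(pair, "dwi_pair"))
  lo <- pair$s_low$data
  hi <- pair$s_high$data
  valid <- lo > noise_floor & hi > noise_floor
  valid[is.na(valid)] <- FALSE
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "seg_mask"))
    if (!same_grid(mask, pair$s_low))
      stop_lq("lq_geometry_error", "mask grid does not match the DWI grid")
    valid <- valid & mask$mask
  }
  if (!any(valid))
    stop_lq("lq_data_error",
            "no voxel has strictly positive signal in both DWI volumes")
  adc <- array(NA_real_, dim(lo))
  adc[valid] <- log(lo[valid] / hi[valid]) / (pair$b_high - pair$b_low) * scale
  if (floor_zero) adc[valid & adc < 0] <- 0
  out <- image_volume(adc, pair$s_low$spacing, pair$s_low$origin)
  attr(out, "valid") <- seg_mask(valid, pair$s_low$spacing, pair$s_low$origin)
  out
}
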