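#' Segment enhanced tissue on a DCE subtraction volume
#'
#' Two-compartment 1-D k-means over the intensities inside the operator's box;
#' the upper-centroid cluster (voxels at or above the decision cut-off) forms
#' the enhanced-tissue mask. Voxels outside the box are excluded.
#'
#' @param dce_sub `image_volume`, DCE subtraction (post- minus pre-contrast).
#' @param box [index_box()] drawn around the lesion; every side must span at
#'   least 2 voxels.
#' @param seed passed to [kmeans_1d()].
#' @param largest_component keep only the largest 26-connected component of
#'   the enhanced cluster (default FALSE: all upper-cluster voxels).
#' @return A `seg_mask` on the DCE grid with attribute `cutoff`.
#' @export
segment_enhanced_dce <- function(dce_sub, box, seed = 1L,
                                 largest_component = FALSE) {
  stopifnot(inherits(dce_sub, "image_volume"), inherits(box, "index_box"))
  if (any(box$hi - box$lo < 1L))
    stop_lq("lq_argument_error", "box sides must span at least 2 voxels")
  inbox <- box_mask(box, dce_sub)
  km <- kmeans_1d(dce_sub$data[inbox], 2, seed = seed)
  cutoff <- km$cutoffs[1]
  m <- inbox & !is.na(dce_sub$data) & dce_sub$data >= cutoff
  if (largest_component) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  out <- seg_mask(m, dce_sub$spacing, dce_sub$origin)
  attr(out, "cutoff") <- cutoff
  out
}

#' Exclude the low-signal compartment on DWI b0
#'
#' Three-compartment 1-D k-means over the in-region b0 intensities. The
#' compartments are, in ascending signal: (1) noise, fat and fibrous tissue,
#' (2) high-cellularity tumor, (3) cyst/necrosis/fluid. The decision boundary
#' between compartments 1 and 2 is the lower cut-off; the returned mask keeps
#' region voxels with intensity at or above it (compartments 2 and 3).
#'
#' @param b0 `image_volume`, DWI b = 0 signal.
#' @param region `seg_mask` restricting the classification (the resampled
#'   DCE enhanced-tissue mask).
#' @param seed passed to [kmeans_1d()].
#' @param trim fraction of extreme intensities trimmed at each end before
#'   fitting the cluster model (default 0.01). A handful of noise-floor
#'   voxels can otherwise capture a whole cluster and displace the cut-offs;
#'   the cut-offs are still applied to every region voxel.
#' @return List with `lower_cutoff` and `mask` (`seg_mask`).
#' @export
classify_b0 <- function(b0, region, seed = 1L, trim = 0.01) {
  stopifnot(inherits(b0, "image_volume"), inherits(region, "seg_mask"))
  if (!same_grid(b0, region))
    stop_lq("lq_geometry_error", "region grid does not match the b0 grid")
  if (!any(region$mask))
    stop_lq("lq_argument_error", "region is empty")
  km <- kmeans_1d(trim_extremes(b0$data[region$mask], trim), 3, seed = seed)
  cutoff <- km$cutoffs[1]
  m <- region$mask & !is.na(b0$data) & b0$data >= cutoff
  list(lower_cutoff = cutoff,
       mask = seg_mask(m, b0$spacing, b0$origin))
}

#' Exclude the high-signal compartment on the ADC map
#'
#' Mirror of [classify_b0()] on ADC intensities: compartments in ascending
#' ADC are (1) fat/fibrous, (2) high-cellularity tumor, (3)
#' cyst/necrosis/fluid. The boundary between compartments 2 and 3 is the
#' upper cut-off; the mask keeps region voxels at or below it (compartments 1
#' and 2).
#'
#' @param adc `image_volume`, ADC map.
#' @param region `seg_mask` restricting the classification.
#' @param seed passed to [kmeans_1d()].
#' @inheritParams classify_b0
#' @return List with `upper_cutoff` and `mask` (`seg_mask`).
#' @export
classify_adc <- function(adc, region, seed = 1L, trim = 0.01) {
  stopifnot(inherits(adc, "image_volume"), inherits(region, "seg_mask"))
  if (!same_grid(adc, region))
    stop_lq("lq_geometry_error", "region grid does not match the ADC grid")
  if (!any(region$mask))
    stop_lq("lq_argument_error", "region is empty")
  km <- kmeans_1d(trim_extremes(adc$data[region$mask], trim), 3, seed = seed)
  cutoff <- km$cutoffs[2]
  m <- region$mask & !is.na(adc$data) & adc$data <= cutoff
  list(upper_cutoff = cutoff,
       mask = seg_mask(m, adc$spacing, adc$origin))
}

#' Semi-automated segmentation of the ADC functional volume (V_ADC)
#'
#' Composes the full procedure: (a) enhanced tissue is segmented inside the
#' operator's box on the DCE subtraction volume by 2-compartment k-means;
#' (b) the enhanced mask is resampled onto the DWI grid (nearest neighbour);
#' (c) within it, 3-compartment k-means on DWI b0 excludes the low-signal
#' compartment (noise/fat/fibrous); (d) 3-compartment k-means on the ADC map
#' excludes the high-signal compartment (cyst/necrosis/fluid); (e) the
#' overlap of the two binary masks is the probable spatial extension of the
#' high-cellularity functional volume V_ADC.
#'
#' @param dce_sub `image_volume`, DCE subtraction volume (may be on a finer
#'   grid than the DWI volumes).
#' @param b0 `image_volume`, DWI b = 0 volume.
#' @param adc `image_volume`, ADC map on the DWI grid.
#' @param box [index_box()] on the DCE grid containing the lesion.
#' @param seed passed to the k-means steps.
#' @param largest_component passed to [segment_enhanced_dce()].
#' @param trim passed to [classify_b0()] and [classify_adc()].
#' @return Object of class `vadc_result`: `enhanced_mask` (DCE grid),
#'   `region_mask` (enhanced resampled to DWI grid), `b0_mask`, `adc_mask`,
#'   `vadc_mask`, `v_adc_cc`, `b0_lower_cutoff`, `adc_upper_cutoff`, and
#'   per-stage voxel `counts`.
#' @export
segment_vadc <- function(dce_sub, b0, adc, box, seed = 1L,
                         largest_component = FALSE, trim = 0.01) {
  stopifnot(inherits(b0, "image_volume"), inherits(adc, "image_volume"))
  if (!same_grid(b0, adc))
    stop_lq("lq_geometry_error", "b0 and ADC must share the DWI grid")
  enhanced <- segment_enhanced_dce(dce_sub, box, seed = seed,
                                   largest_component = largest_component)
  region <- resample_mask_to_grid(enhanced, b0)
  if (!any(region$mask))
    stop_lq("lq_empty_segmentation_error",
            "enhanced-tissue mask is empty after resampling to the DWI grid")
  cb0 <- classify_b0(b0, region, seed = seed, trim = trim)
  cadc <- classify_adc(adc, region, seed = seed, trim = trim)
  vm <- cb0$mask$mask & cadc$mask$mask
  if (!any(vm))
    stop_lq("lq_empty_segmentation_error",
            "V_ADC is empty: the b0 and ADC masks do not overlap")
  vadc <- seg_mask(vm, b0$spacing, b0$origin)
  structure(list(
    enhanced_mask = enhanced, region_mask = region,
    b0_mask = cb0$mask, adc_mask = cadc$mask, vadc_mask = vadc,
    v_adc_cc = mask_volume_cc(vadc),
    b0_lower_cutoff = cb0$lower_cutoff,
    adc_upper_cutoff = cadc$upper_cutoff,
    counts = c(enhanced = sum(enhanced$mask), region = sum(region$mask),
               b0 = sum(cb0$mask$mask), adc = sum(cadc$mask$mask),
               vadc = sum(vm))
  ), class = "vadc_result")
}

# drop the extreme `trim` fraction at each end for robust cutoff fitting;
# falls back to the full sample if trimming would leave < 3 distinct values
trim_extremes <- function(values, trim) {
  values <- values[!is.na(values)]
  if (trim <= 0) return(values)
  qs <- stats::quantile(values, c(trim, 1 - trim), names = FALSE, type = 7)
  kept <- values[values >= qs[1] & values <= qs[2]]
  if (length(unique(kept)) >= 3) kept else values
}

#' @export
print.vadc_result <- function(x, ...) {
  cat(sprintf("<vadc_result> V_ADC = %.3f cc (%d voxels)\n",
              x$v_adc_cc, x$counts[["vadc"]]))
  cat(sprintf("  b0 lower cutoff = %.4g, ADC upper cutoff = %.4g\n",
              x$b0_lower_cutoff, x$adc_upper_cutoff))
  cat("  stage voxel counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
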