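#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one place; the serialized config
#' is embedded in every pipeline report for auditability.
#'
#' @param b_low,b_high DWI b-values (s/mm^2).
#' @param adc_output_scale multiplicative scale of the computed ADC map
#'   (default 1e6: printed clinical convention, see [compute_adc_map()]).
#' @param adc_noise_floor,adc_floor_zero passed to [compute_adc_map()].
#' @param kmeans_seed,kmeans_tol,kmeans_exact_n 1-D k-means controls
#'   (see [kmeans_1d()]).
#' @param kmeans_trim robust-fit trim fraction for the compartment cut-offs
#'   (see [classify_b0()]; default 0.01).
#' @param largest_component keep only the largest connected component of the
#'   DCE enhanced-tissue mask (default FALSE: all upper-cluster voxels).
#' @param mtv_bg_fraction adaptive MTV threshold fraction (default 0.41).
#' @param mtv_connectivity connected-component connectivity for MTV (26).
#' @param psf_fwhm_mm PET scanner PSF FWHM for partial-volume correction
#'   (default 6 mm).
#' @param bins histogram bin count for entropy/uniformity (default 64).
#' @param surface_mode `"mesh"` (anti-aliased marching-tetrahedra
#'   isosurface) or `"faces"` (exposed voxel faces).
#' @param smooth_sigma anti-alias smoothing (voxels) for mesh surfaces
#'   (default 0.7).
#' @param tld_unit_factor unit factor of the TLD product (default 1e-2:
#'   mm^2 * cm^3 -> cm^5).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(b_low = 0, b_high = 900,
                            adc_output_scale = 1e6, adc_noise_floor = 0,
                            adc_floor_zero = FALSE,
                            kmeans_seed = 1L, kmeans_tol = 1e-8,
                            kmeans_exact_n = 2048L, kmeans_trim = 0.01,
                            largest_component = FALSE,
                            mtv_bg_fraction = 0.41, mtv_connectivity = 26,
                            psf_fwhm_mm = 6, bins = 64L,
                            surface_mode = c("mesh", "faces"),
                            smooth_sigma = 0.7, tld_unit_factor = 1e-2) {
  surface_mode <- match.arg(surface_mode)
  structure(list(b_low = b_low, b_high = b_high,
                 adc_output_scale = adc_output_scale,
                 adc_noise_floor = adc_noise_floor,
                 adc_floor_zero = adc_floor_zero,
                 kmeans_seed = as.integer(kmeans_seed),
                 kmeans_tol = kmeans_tol,
                 kmeans_exact_n = as.integer(kmeans_exact_n),
                 kmeans_trim = kmeans_trim,
                 largest_component = largest_component,
                 mtv_bg_fraction = mtv_bg_fraction,
                 mtv_connectivity = mtv_connectivity,
                 psf_fwhm_mm = psf_fwhm_mm, bins = as.integer(bins),
                 surface_mode = surface_mode, smooth_sigma = smooth_sigma,
                 tld_unit_factor = tld_unit_factor),
            class = "pipeline_config")
}

#' Run the full dual-modality quantification pipeline on one study
#'
#' MR side: ADC map from the two-point DWI pair, V_ADC segmentation
#' (DCE-seeded k-means compartment exclusion), macroscopic MR features
#' (V_ADC, ADC_mean, ADC_min, TLD) and the 22-feature MR vector. PET side:
#' SUV conversion, MTV segmentation, partial-volume-corrected SUV_mean, TLG,
#' and the 22-feature PET vector. The report carries all intermediate masks,
#' cut-offs and the serialized configuration; a rerun with identical inputs
#' and config is bit-identical.
#'
#' @param study a `synthetic_study`, or any list with elements `dce_sub`,
#'   `dwi_b0`, `dwi_b900` (or a precomputed `adc`), `pet_activity`,
#'   `pet_meta`.
#' @param dce_box [index_box()] on the DCE grid around the lesion; defaults
#'   to [lesion_box()] for synthetic studies.
#' @param pet_box [index_box()] on the PET grid; same default.
#' @param config a [pipeline_config()].
#' @param mr_only,pet_only restrict to one modality.
#' @return Object of class `lesion_report`: `features` (one-row data.frame,
#'   columns `pet_*` and/or `mr_*`), `mr` (list: `adc`, `vadc`,
#'   `macroscopic`), `pet` (list: `suv`, `mtv`, `suv_mean_pvc`, `rc`,
#'   `macroscopic`), `config`.
#' @export
run_pipeline <- function(study, dce_box = NULL, pet_box = NULL,
                         config = pipeline_config(), mr_only = FALSE,
                         pet_only = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (mr_only && pet_only)
    stop_lq("lq_argument_error", "mr_only and pet_only are exclusive")
  is_phantom <- inherits(study, "synthetic_study")
  mr <- pet <- NULL
  feature_df <- NULL

  if (!pet_only) {
    for (nm in c("dce_sub", "dwi_b0"))
      if (is.null(study[[nm]]))
        stop_lq("lq_argument_error", "study lacks '%s' (MR side)", nm)
    if (is.null(dce_box)) {
      if (!is_phantom)
        stop_lq("lq_argument_error", "dce_box required for non-phantom input")
      dce_box <- lesion_box(study, "dce")
    }
    adc <- study$adc
    if (is.null(adc)) {
      if (is.null(study$dwi_b900))
        stop_lq("lq_argument_error",
                "study lacks 'dwi_b900' and no precomputed 'adc' given")
      adc <- compute_adc_map(
        dwi_pair(study$dwi_b0, study$dwi_b900, config$b_low, config$b_high),
        scale = config$adc_output_scale,
        noise_floor = config$adc_noise_floor,
        floor_zero = config$adc_floor_zero)
    }
    vadc <- segment_vadc(study$dce_sub, study$dwi_b0, adc, dce_box,
                         seed = config$kmeans_seed,
                         largest_component = config$largest_component,
                         trim = config$kmeans_trim)
    vals <- adc$data[vadc$vadc_mask$mask]
    macro_mr <- c(v_adc_cc = vadc$v_adc_cc,
                  adc_mean = mean(vals), adc_min = min(vals),
                  tld_cm5_s = compute_tld(mean(vals), vadc$v_adc_cc,
                                          config$tld_unit_factor))
    fv_mr <- extract_features(adc, vadc$vadc_mask, macro_mr, "MR",
                              bins = config$bins,
                              surface_mode = config$surface_mode,
                              smooth_sigma = config$smooth_sigma)
    mr <- list(adc = adc, vadc = vadc, macroscopic = macro_mr,
               features = fv_mr)
  }

  if (!mr_only) {
    for (nm in c("pet_activity", "pet_meta"))
      if (is.null(study[[nm]]))
        stop_lq("lq_argument_error", "study lacks '%s' (PET side)", nm)
    if (is.null(pet_box)) {
      if (!is_phantom)
        stop_lq("lq_argument_error", "pet_box required for non-phantom input")
      pet_box <- lesion_box(study, "pet")
    }
    suv <- compute_suv_volume(study$pet_activity, study$pet_meta)
    mtv <- segment_mtv(suv, pet_box, bg_fraction = config$mtv_bg_fraction,
                       connectivity = config$mtv_connectivity,
                       seed = config$kmeans_seed)
    pvc <- apply_pvc(mtv$suv_mean, mtv$mtv_cc,
                     psf_fwhm_mm = config$psf_fwhm_mm)
    macro_pet <- c(mtv_cc = mtv$mtv_cc, suv_mean_pvc = as.numeric(pvc),
                   suv_max = mtv$suv_max,
                   tlg_g = compute_tlg(as.numeric(pvc), mtv$mtv_cc))
    fv_pet <- extract_features(suv, mtv$mask, macro_pet, "PET",
                               bins = config$bins,
                               surface_mode = config$surface_mode,
                               smooth_sigma = config$smooth_sigma)
    pet <- list(suv = suv, mtv = mtv, suv_mean_pvc = as.numeric(pvc),
                rc = attr(pvc, "rc"), macroscopic = macro_pet,
                features = fv_pet)
  }

  parts <- list()
  if (!is.null(pet)) parts <- c(parts, list(as.data.frame(pet$features)))
  if (!is.null(mr)) parts <- c(parts, list(as.data.frame(mr$features)))
  feature_df <- do.call(cbind, parts)

  structure(list(features = feature_df, mr = mr, pet = pet,
                 config = config,
                 clinical = if (is_phantom) study$clinical else NULL),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat("<lesion_report>\n")
  if (!is.null(x$pet))
    cat(sprintf("  PET: MTV = %.2f cc, PVC SUV_mean = %.2f g/cc, SUV_max = %.2f, TLG = %.2f g\n",
                x$pet$macroscopic["mtv_cc"], x$pet$macroscopic["suv_mean_pvc"],
                x$pet$macroscopic["suv_max"], x$pet$macroscopic["tlg_g"]))
  if (!is.null(x$mr))
    cat(sprintf("  MR:  V_ADC = %.2f cc, ADC_mean = %.0f, ADC_min = %.0f, TLD = %.2f cm^5/s\n",
                x$mr$macroscopic["v_adc_cc"], x$mr$macroscopic["adc_mean"],
                x$mr$macroscopic["adc_min"], x$mr$macroscopic["tld_cm5_s"]))
  cat(sprintf("  features: %d columns\n", ncol(x$features)))
  invisible(x)
}

#' Build a cohort feature table from a list of studies
#'
#' Runs [run_pipeline()] on every study of a cohort and binds the 44 feature
#' columns with the clinical labels into one data.frame suitable for
#' [run_screen()].
#'
#' @param cohort a `phantom_cohort` (or plain list of `synthetic_study`).
#' @param config a [pipeline_config()].
#' @return A data.frame with class `cohort_table`, one row per lesion.
#' @export
build_cohort_table <- function(cohort, config = pipeline_config()) {
  studies <- if (inherits(cohort, "phantom_cohort")) cohort$studies else cohort
  rows <- lapply(seq_along(studies), function(i) {
    rep_i <- run_pipeline(studies[[i]], config = config)
    cbind(rep_i$features, studies[[i]]$clinical)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}
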