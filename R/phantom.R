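#' Configuration for the synthetic multimodal breast-lesion phantom
#'
#' Defines a three-compartment lesion (fat/fibrous, high-cellularity tumor,
#' cyst/necrosis/fluid) embedded in background on co-registered DWI, DCE and
#' PET grids. Geometry is a sphere (optionally distorted to an ellipsoid)
#' with a fluid core, a tumor shell and a fat/fibrous rim whose volume
#' fractions are `compartment_fractions`. Signal orderings follow the
#' compartment model: on DWI b0 and on ADC, fat/fibrous < tumor < fluid;
#' on DCE subtraction, every lesion compartment enhances above background.
#'
#' ADC values are carried on the printed clinical scale (magnitudes ~10^2 to
#' ~2.5x10^3 in units written mm^2/s, physically 10^-6 mm^2/s);
#' `adc_decay_scale` converts them to physical units inside the exponential
#' decay law `b900 = b0 * exp(-(b_high - b_low) * ADC * adc_decay_scale)`.
#'
#' @param dwi_shape,dwi_spacing DWI grid (voxels; mm). Defaults 48 x 48 x 24
#'   at 1.4 x 1.4 x 3 mm (axial EPI-like geometry, 3 mm slices).
#' @param dce_spacing DCE grid spacing (mm); the DCE grid covers the DWI
#'   field of view at finer resolution (default 0.84 x 0.84 x 2.5 mm) so that
#'   mask resampling is exercised.
#' @param pet_shape,pet_spacing PET grid (default 24 x 24 x 18 at 4 mm
#'   isotropic).
#' @param lesion_diameter_cm sphere-equivalent lesion diameter (cm).
#' @param diameter_range_cm admissible diameter bounds (cm); cohort sampling
#'   draws inside them.
#' @param compartment_fractions length-3, fractions of the lesion volume in
#'   (fat/fibrous, tumor, fluid); must sum to 1.
#' @param signal_levels list with numeric vectors `dce`, `b0`, `suv`, each
#'   named (`background`, `fibrous`, `tumor`, `fluid`): mean intensities per
#'   compartment and background.
#' @param adc_levels named numeric: true ADC per compartment and background
#'   (printed scale).
#' @param adc_sigma named numeric: intra-compartment biological ADC spread
#'   (printed scale); drives histogram heterogeneity (entropy etc.).
#' @param noise_sigma named numeric `c(dce=, dwi=, pet=)`: additive
#'   measurement noise scale per modality (`pet` in SUV units), all >= 0.
#' @param noise_model `"gaussian"` (additive, default) or `"rician"`
#'   (magnitude-image model) for the DWI volumes.
#' @param ellipsoid_ratio length-3 axis ratios distorting the sphere
#'   (volume-preserving after normalisation; default `c(1, 1, 1)`).
#' @param b_values `c(b_low, b_high)` in s/mm^2 (default `c(0, 900)`).
#' @param adc_decay_scale printed-ADC to physical-ADC factor (default 1e-6).
#' @param pet_meta a [pet_meta()]; default is a 70 kg patient injected with
#'   259 MBq (3.7 MBq/kg), 2 MBq residual, 60 min uptake.
#' @param seed integer seed; studies are bit-reproducible given the config.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(
    dwi_shape = c(48, 48, 24), dwi_spacing = c(1.4, 1.4, 3),
    dce_spacing = c(0.84, 0.84, 2.5),
    pet_shape = c(24, 24, 18), pet_spacing = c(4, 4, 4),
    lesion_diameter_cm = 2.4, diameter_range_cm = c(0.61, 3.88),
    compartment_fractions = c(fibrous = 0.2, tumor = 0.6, fluid = 0.2),
    signal_levels = list(
      dce = c(background = 5, fibrous = 95, tumor = 110, fluid = 100),
      b0 = c(background = 25, fibrous = 60, tumor = 160, fluid = 320),
      suv = c(background = 0.8, fibrous = 1.5, tumor = 8, fluid = 0.6)
    ),
    adc_levels = c(background = 1600, fibrous = 400, tumor = 900,
                   fluid = 2500),
    adc_sigma = c(background = 0, fibrous = 30, tumor = 60, fluid = 100),
    noise_sigma = c(dce = 2, dwi = 3, pet = 0.15),
    noise_model = c("gaussian", "rician"),
    ellipsoid_ratio = c(1, 1, 1),
    b_values = c(0, 900), adc_decay_scale = 1e-6,
    pet_meta = NULL, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (any(dwi_shape < 8) || any(pet_shape < 8))
    stop_lq("lq_config_error", "grid shapes must all be >= 8 voxels per axis")
  if (abs(sum(compartment_fractions) - 1) > 1e-9)
    stop_lq("lq_config_error", "compartment_fractions must sum to 1")
  if (any(compartment_fractions < 0))
    stop_lq("lq_config_error", "compartment_fractions must be non-negative")
  if (lesion_diameter_cm < diameter_range_cm[1] - 1e-12 ||
      lesion_diameter_cm > diameter_range_cm[2] + 1e-12)
    stop_lq("lq_config_error",
            "lesion diameter %.3g cm outside configured bounds [%g, %g]",
            lesion_diameter_cm, diameter_range_cm[1], diameter_range_cm[2])
  if (any(noise_sigma < 0))
    stop_lq("lq_config_error", "noise_sigma must be >= 0")
  comp <- c("background", "fibrous", "tumor", "fluid")
  for (nm in c("dce", "b0", "suv")) {
    if (!all(comp %in% names(signal_levels[[nm]])))
      stop_lq("lq_config_error", "signal_levels$%s must name %s", nm,
              paste(comp, collapse = ", "))
    signal_levels[[nm]] <- signal_levels[[nm]][comp]
  }
  if (!all(comp %in% names(adc_levels)) || !all(comp %in% names(adc_sigma)))
    stop_lq("lq_config_error", "adc_levels and adc_sigma must name %s",
            paste(comp, collapse = ", "))
  adc_levels <- adc_levels[comp]
  adc_sigma <- adc_sigma[comp]
  # compartment signal orderings of the three-class model
  b0l <- signal_levels$b0
  if (!(b0l["fibrous"] < b0l["tumor"] && b0l["tumor"] < b0l["fluid"]))
    stop_lq("lq_config_error",
            "DWI b0 ordering violated: need fibrous < tumor < fluid")
  if (!(adc_levels["fibrous"] < adc_levels["tumor"] &&
        adc_levels["tumor"] < adc_levels["fluid"]))
    stop_lq("lq_config_error",
            "ADC ordering violated: need fibrous < tumor < fluid")
  dcel <- signal_levels$dce
  if (!all(dcel[c("fibrous", "tumor", "fluid")] > dcel["background"]))
    stop_lq("lq_config_error",
            "DCE ordering violated: lesion compartments must enhance above background")
  if (is.null(pet_meta))
    pet_meta <- pet_meta(injected_activity_mbq = 259,
                         residual_activity_mbq = 2,
                         body_weight_g = 70000,
                         injection_time = 0, scan_time = 60)
  structure(list(
    dwi_shape = as.integer(dwi_shape), dwi_spacing = as.numeric(dwi_spacing),
    dce_spacing = as.numeric(dce_spacing),
    pet_shape = as.integer(pet_shape), pet_spacing = as.numeric(pet_spacing),
    lesion_diameter_cm = lesion_diameter_cm,
    diameter_range_cm = diameter_range_cm,
    compartment_fractions = compartment_fractions,
    signal_levels = signal_levels, adc_levels = adc_levels,
    adc_sigma = adc_sigma, noise_sigma = noise_sigma,
    noise_model = noise_model, ellipsoid_ratio = as.numeric(ellipsoid_ratio),
    b_values = as.numeric(b_values), adc_decay_scale = adc_decay_scale,
    pet_meta = pet_meta, seed = as.integer(seed)
  ), class = "phantom_config")
}

# compartment label array on an arbitrary grid:
# 0 background, 1 fibrous rim, 2 tumor shell, 3 fluid core
compartment_labels <- function(shape, spacing, center_mm, radius_mm,
                               fractions, axes) {
  axes <- axes / prod(axes)^(1 / 3)  # volume-preserving distortion
  xs <- ((seq_len(shape[1]) - 1) * spacing[1] - center_mm[1]) / axes[1]
  ys <- ((seq_len(shape[2]) - 1) * spacing[2] - center_mm[2]) / axes[2]
  zs <- ((seq_len(shape[3]) - 1) * spacing[3] - center_mm[3]) / axes[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  r_fluid <- radius_mm * fractions[3]^(1 / 3)
  r_tumor <- radius_mm * (fractions[3] + fractions[2])^(1 / 3)
  lab <- array(0L, shape)
  lab[d2 <= radius_mm^2] <- 1L
  lab[d2 <= r_tumor^2] <- 2L
  lab[d2 <= r_fluid^2] <- 3L
  lab
}

#' Generate one synthetic multimodal study
#'
#' Builds a three-compartment lesion on the DWI, DCE and PET grids with
#' modality-consistent signal. Before noise, the DWI pair satisfies the
#' exponential decay law exactly:
#' `b900 = b0 * exp(-(b_high - b_low) * ADC_true * adc_decay_scale)`,
#' so the ADC map computed from the noise-free volumes reproduces the stored
#' true ADC field voxelwise. Ground-truth compartment masks (DWI grid) are
#' recorded, the compartment masks are disjoint and their union is the
#' whole-lesion mask. Deterministic for a fixed config (seed included).
#'
#' @param config a [phantom_config()].
#' @param clinical optional 1-row data.frame of clinical labels (as from
#'   [generate_clinical_labels()]); drawn from the default prevalences when
#'   `NULL`.
#' @return Object of class `synthetic_study`: volumes `dce_sub`, `dwi_b0`,
#'   `dwi_b900`, `adc_truth`, `pet_activity`; `pet_meta`; `truth_masks`
#'   (list `fibrous`, `tumor`, `fluid`, `whole` on the DWI grid);
#'   `truth_masks_pet` (`tumor`, `whole` on the PET grid); `clinical`;
#'   `geometry` (lesion centre/radius); `config`.
#' @export
generate_study <- function(config, clinical = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_local_seed(config$seed, {
    radius_mm <- config$lesion_diameter_cm * 10 / 2
    dwi_extent <- config$dwi_shape * config$dwi_spacing
    if (2 * radius_mm > min(dwi_extent) - 2 * max(config$dwi_spacing))
      stop_lq("lq_geometry_error",
              "lesion (diameter %.3g cm) does not fit the DWI grid",
              config$lesion_diameter_cm)
    center <- (config$dwi_shape - 1) * config$dwi_spacing / 2 +
      stats::runif(3, -1, 1)
    fr <- config$compartment_fractions
    lev <- config$signal_levels
    ax <- config$ellipsoid_ratio

    lab_dwi <- compartment_labels(config$dwi_shape, config$dwi_spacing,
                                  center, radius_mm, fr, ax)
    # ADC truth: compartment level + intra-compartment biological spread
    n_dwi <- prod(config$dwi_shape)
    adc <- config$adc_levels[lab_dwi + 1L] +
      config$adc_sigma[lab_dwi + 1L] * stats::rnorm(n_dwi)
    adc <- array(pmax(adc, 1), config$dwi_shape)
    b0_clean <- array(lev$b0[lab_dwi + 1L], config$dwi_shape)
    db <- config$b_values[2] - config$b_values[1]
    b900_clean <- b0_clean * exp(-db * adc * config$adc_decay_scale)
    b0 <- add_noise(b0_clean, config$noise_sigma["dwi"], config$noise_model)
    b900 <- add_noise(b900_clean, config$noise_sigma["dwi"],
                      config$noise_model)

    dce_shape <- pmax(8L, as.integer(ceiling(dwi_extent / config$dce_spacing)))
    lab_dce <- compartment_labels(dce_shape, config$dce_spacing, center,
                                  radius_mm, fr, ax)
    dce <- array(lev$dce[lab_dce + 1L], dce_shape)
    dce <- add_noise(dce, config$noise_sigma["dce"], "gaussian")

    # PET grid centred on the same world position
    pet_origin <- center - (config$pet_shape - 1) * config$pet_spacing / 2
    lab_pet <- compartment_labels(config$pet_shape, config$pet_spacing,
                                  center - pet_origin, radius_mm, fr, ax)
    suv_to_conc <- net_activity_mbq(config$pet_meta, warn = FALSE) /
      config$pet_meta$body_weight_g
    act <- array(lev$suv[lab_pet + 1L], config$pet_shape)
    act <- act + config$noise_sigma["pet"] * stats::rnorm(length(act))
    act <- pmax(act, 0) * suv_to_conc

    sp <- config$dwi_spacing
    masks <- list(
      fibrous = seg_mask(lab_dwi == 1L, sp),
      tumor = seg_mask(lab_dwi == 2L, sp),
      fluid = seg_mask(lab_dwi == 3L, sp),
      whole = seg_mask(lab_dwi > 0L, sp)
    )
    masks_pet <- list(
      tumor = seg_mask(lab_pet == 2L, config$pet_spacing, pet_origin),
      whole = seg_mask(lab_pet > 0L, config$pet_spacing, pet_origin)
    )
    if (is.null(clinical)) clinical <- generate_clinical_labels(1)
    structure(list(
      dce_sub = image_volume(dce, config$dce_spacing),
      dwi_b0 = image_volume(array(b0, config$dwi_shape), sp),
      dwi_b900 = image_volume(array(b900, config$dwi_shape), sp),
      adc_truth = image_volume(adc, sp),
      pet_activity = image_volume(act, config$pet_spacing, pet_origin),
      pet_meta = config$pet_meta,
      truth_masks = masks, truth_masks_pet = masks_pet,
      clinical = clinical,
      geometry = list(center_mm = center, radius_mm = radius_mm,
                      axes = ax / prod(ax)^(1 / 3)),
      config = config
    ), class = "synthetic_study")
  })
}

add_noise <- function(x, sigma, model) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  if (model == "rician") {
    array(sqrt((x + sigma * stats::rnorm(length(x)))^2 +
                 (sigma * stats::rnorm(length(x)))^2), d)
  } else {
    array(x + sigma * stats::rnorm(length(x)), d)
  }
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> lesion diameter %.2f cm, subtype %s, pCR %s\n",
              x$geometry$radius_mm / 5, x$clinical$subtype,
              x$clinical$pcr))
  cat(sprintf("  DWI %s | DCE %s | PET %s\n",
              paste(dim(x$dwi_b0$data), collapse = "x"),
              paste(dim(x$dce_sub$data), collapse = "x"),
              paste(dim(x$pet_activity$data), collapse = "x")))
  invisible(x)
}

#' Draw clinical labels for simulated patients
#'
#' Samples molecular subtype, hormone-receptor expression, c-erbB-2 status,
#' MiB-1 proliferation index and pCR with the cohort prevalences used as
#' defaults throughout the package: subtype (Luminal A 24%, Luminal B 21%,
#' HER2+ 13%, triple-negative 42%), MiB-1 >= 18% in 81%, pCR 42%. ER/PR
#' percentages are drawn so that [classify_subtype()] reproduces the sampled
#' subtype exactly (positivity means expression > 0%).
#'
#' Uses the current RNG stream; seed externally for reproducibility.
#'
#' @param n number of patients.
#' @param subtype_prob named prevalence vector for the four subtypes.
#' @param pcr_prob,mib1_pos_prob prevalences of pCR and MiB-1 positivity.
#' @param exact_counts allocate subtype and pCR counts deterministically
#'   (largest-remainder rounding of `n * prob`) instead of iid draws.
#' @return data.frame with columns `er_percent`, `pr_percent`,
#'   `cerbb2_positive`, `mib1_percent`, `pcr`, `subtype`.
#' @export
generate_clinical_labels <- function(
    n,
    subtype_prob = c(LuminalA = 0.24, LuminalB = 0.21, HER2pos = 0.13,
                     TripleNegative = 0.42),
    pcr_prob = 0.42, mib1_pos_prob = 0.81, exact_counts = TRUE) {
  if (n < 1) stop_lq("lq_argument_error", "n must be >= 1")
  subtype_prob <- subtype_prob / sum(subtype_prob)
  if (exact_counts && n > 1) {
    cnt <- largest_remainder(n, subtype_prob)
    subtype <- sample(rep(names(subtype_prob), cnt))
    pcr <- rep(FALSE, n)
    pcr[sample.int(n, round(n * pcr_prob))] <- TRUE
  } else {
    subtype <- sample(names(subtype_prob), n, replace = TRUE,
                      prob = subtype_prob)
    pcr <- stats::runif(n) < pcr_prob
  }
  luminal <- subtype %in% c("LuminalA", "LuminalB")
  er_pos <- luminal & stats::runif(n) < 0.85
  pr_pos <- luminal & stats::runif(n) < 0.60
  neither <- luminal & !er_pos & !pr_pos
  er_pos[neither] <- TRUE
  clipnorm <- function(k, mu, sd, lo, hi) pmin(hi, pmax(lo, round(stats::rnorm(k, mu, sd))))
  er <- ifelse(er_pos, clipnorm(n, 71, 31, 1, 100), 0)
  pr <- ifelse(pr_pos, clipnorm(n, 38, 38, 1, 100), 0)
  mib_pos <- stats::runif(n) < mib1_pos_prob
  mib <- ifelse(mib_pos, clipnorm(n, 44, 15, 18, 100),
                clipnorm(n, 15, 4, 1, 17))
  data.frame(er_percent = er, pr_percent = pr,
             cerbb2_positive = subtype %in% c("LuminalB", "HER2pos"),
             mib1_percent = mib, pcr = pcr, subtype = subtype,
             stringsAsFactors = FALSE)
}

largest_remainder <- function(n, prob) {
  raw <- n * prob
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt
}

#' Generate a synthetic cohort of multimodal studies
#'
#' Draws `n` studies with lesion diameters sampled inside the configured
#' bounds (log-normal, median ~1.4 cm) and clinical labels at the default
#' prevalences (deterministic proportions up to rounding). `effect_spec`
#' injects label-linked effects at the image level, e.g. increased
#' intra-tumor ADC heterogeneity for pCR-positive lesions; with
#' `effect_spec = NULL` feature distributions are identical across label
#' groups.
#'
#' @param n cohort size (>= 2).
#' @param config a [phantom_config()]; per-study seeds are derived from
#'   `config$seed`.
#' @param effect_spec `NULL`, or a list of effects, each a list with fields
#'   `label` (`"pcr"`, `"tn"` or `"er_positive"`: the group carrying the
#'   effect), `param` (`"adc_sigma_tumor"`, `"adc_tumor"`, `"suv_tumor"` or
#'   `"diameter"`), `value`, and `mode` (`"multiply"`, default, or `"add"`).
#' @return Object of class `phantom_cohort`: list with `studies`, `labels`
#'   (data.frame) and `config`.
#' @export
generate_cohort <- function(n, config = phantom_config(),
                            effect_spec = NULL) {
  if (n < 2) stop_lq("lq_argument_error", "cohort size must be >= 2")
  stopifnot(inherits(config, "phantom_config"))
  labels <- with_local_seed(config$seed, generate_clinical_labels(n))
  diam <- with_local_seed(config$seed + 1L,
                          sample_diameters(n, config$diameter_range_cm))
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- config
    ci$seed <- config$seed + 101L * i
    ci$lesion_diameter_cm <- diam[i]
    ci <- apply_effects(ci, effect_spec, labels[i, ])
    studies[[i]] <- generate_study(ci, clinical = labels[i, ])
  }
  structure(list(studies = studies, labels = labels, config = config),
            class = "phantom_cohort")
}

sample_diameters <- function(n, range_cm, meanlog = log(1.4), sdlog = 0.5) {
  d <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      x <- stats::rlnorm(1, meanlog, sdlog)
      if (x >= range_cm[1] && x <= range_cm[2]) break
    }
    d[i] <- min(max(x, range_cm[1]), range_cm[2])
  }
  d
}

apply_effects <- function(config, effect_spec, label_row) {
  if (is.null(effect_spec)) return(config)
  in_group <- function(label) switch(label,
    pcr = isTRUE(label_row$pcr),
    tn = label_row$subtype == "TripleNegative",
    er_positive = label_row$er_percent > 0,
    stop_lq("lq_argument_error", "unknown effect label '%s'", label))
  for (ef in effect_spec) {
    if (!in_group(ef$label)) next
    mode <- if (is.null(ef$mode)) "multiply" else ef$mode
    bump <- function(x) if (mode == "add") x + ef$value else x * ef$value
    switch(ef$param,
      adc_sigma_tumor = config$adc_sigma["tumor"] <-
        bump(config$adc_sigma["tumor"]),
      adc_tumor = config$adc_levels["tumor"] <-
        bump(config$adc_levels["tumor"]),
      suv_tumor = config$signal_levels$suv["tumor"] <-
        bump(config$signal_levels$suv["tumor"]),
      diameter = config$lesion_diameter_cm <- min(
        max(bump(config$lesion_diameter_cm), config$diameter_range_cm[1]),
        config$diameter_range_cm[2]),
      stop_lq("lq_argument_error", "unknown effect param '%s'", ef$param))
  }
  config
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d studies\n", length(x$studies)))
  print(table(x$labels$subtype))
  invisible(x)
}

#' Bounding box of the phantom lesion on one of its grids
#'
#' Stands in for the operator-drawn rectangular box: the world-space bounding
#' box of the ground-truth lesion plus a margin, clamped to the grid.
#'
#' @param study a `synthetic_study`.
#' @param grid `"dce"`, `"pet"` or `"dwi"`.
#' @param margin_mm margin added on every side (default 6 mm).
#' @return An [index_box()] on the requested grid.
#' @export
lesion_box <- function(study, grid = c("dce", "pet", "dwi"), margin_mm = 6) {
  grid <- match.arg(grid)
  vol <- switch(grid, dce = study$dce_sub, pet = study$pet_activity,
                dwi = study$dwi_b0)
  g <- study$geometry
  half <- g$radius_mm * g$axes + margin_mm
  d <- dim(vol$data)
  lo <- hi <- integer(3)
  for (a in 1:3) {
    lo[a] <- max(1L, 1L + floor((g$center_mm[a] - half[a] - vol$origin[a]) /
                                  vol$spacing[a]))
    hi[a] <- min(d[a], 1L + ceiling((g$center_mm[a] + half[a] -
                                       vol$origin[a]) / vol$spacing[a]))
  }
  index_box(lo, hi)
}
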