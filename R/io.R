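#' Read a 3-D volume from disk
#'
#' NIfTI (.nii / .nii.gz) is the canonical interchange format. The voxel
#' spacing is taken from the NIfTI pixdim and the origin (world coordinate of
#' the first voxel centre) from the stored affine translation. DICOM series
#' are not supported by this implementation (no DICOM reader in the R
#' dependency stack); requesting one raises a format error.
#'
#' @param path file path.
#' @param format `"nifti"` (default) or `"dicom"` (errors).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom")
    stop_lq("lq_format_error",
            "DICOM series are not supported; convert to NIfTI first")
  if (!file.exists(path))
    stop_lq("lq_format_error", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3 || any(!is.finite(spacing[1:3])) ||
      any(spacing[1:3] <= 0))
    stop_lq("lq_format_error", "missing or invalid voxel spacing in %s", path)
  xf <- RNifti::xform(img)
  origin <- unname(xf[1:3, 4])
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  image_volume(arr, spacing[1:3], origin)
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are written as float64 (lossless round trip for doubles), masks as
#' uint8 on their source grid.
#'
#' @param x an [image_volume()] or [seg_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "seg_mask")) {
    arr <- array(as.integer(x$mask), dim(x$mask))
    dt <- "uint8"
  } else if (inherits(x, "image_volume")) {
    arr <- x$data
    dt <- "double"
  } else {
    stop_lq("lq_argument_error", "x must be an image_volume or seg_mask")
  }
  attr(arr, "pixdim") <- x$spacing
  img <- RNifti::asNifti(arr)
  m <- diag(4)
  m[1, 1] <- x$spacing[1]; m[2, 2] <- x$spacing[2]; m[3, 3] <- x$spacing[3]
  m[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the feature row, macroscopic summaries, segmentation cut-offs,
#' per-stage voxel counts and the full configuration (every output artifact
#' carries the config that produced it).
#'
#' @param report a `lesion_report`.
#' @param path output `.json` path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly if written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "lesion_report"))
  payload <- list(
    features = as.list(report$features),
    config = unclass(report$config),
    package_version = as.character(utils::packageVersion("lesionquant"))
  )
  if (!is.null(report$mr))
    payload$mr <- list(
      macroscopic = as.list(report$mr$macroscopic),
      b0_lower_cutoff = report$mr$vadc$b0_lower_cutoff,
      adc_upper_cutoff = report$mr$vadc$adc_upper_cutoff,
      stage_voxel_counts = as.list(report$mr$vadc$counts))
  if (!is.null(report$pet))
    payload$pet <- list(
      macroscopic = as.list(report$pet$macroscopic),
      mtv_threshold = report$pet$mtv$threshold,
      background = report$pet$mtv$background,
      recovery_coefficient = report$pet$rc)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write cohort screen results to CSV
#'
#' @param screen a `screen_result`.
#' @param path output `.csv` path for the p-value matrix; the test-provenance
#'   matrix goes to `<path>.tests.csv` and the PET-MR pair table (if present)
#'   to `<path>.pairs.csv`.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screen, path) {
  stopifnot(inherits(screen, "screen_result"))
  utils::write.csv(as.data.frame(screen$p), path)
  utils::write.csv(as.data.frame(screen$test),
                   paste0(path, ".tests.csv"))
  if (!is.null(screen$pet_vs_mr))
    utils::write.csv(screen$pet_vs_mr, paste0(path, ".pairs.csv"),
                     row.names = FALSE)
  invisible(path)
}
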