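#' @keywords internal
#' @noRd
stop_lq <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lq_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Error taxonomy shared by the CLI exit-code map:
#   lq_argument_error      invalid argument values / preconditions
#   lq_config_error        inconsistent configuration (e.g. signal orderings)
#   lq_geometry_error      grid mismatch, no spatial overlap, lesion > grid
#   lq_data_error          unusable input data (all-nonpositive signal, ...)
#   lq_degenerate_error    degenerate clustering input (< k distinct values)
#   lq_empty_segmentation_error  segmentation produced an empty mask
#   lq_schema_error        feature-vector naming violations
#   lq_format_error        file-format problems
lq_exit_codes <- c(
  lq_argument_error = 10L,
  lq_config_error = 11L,
  lq_geometry_error = 12L,
  lq_data_error = 13L,
  lq_degenerate_error = 14L,
  lq_empty_segmentation_error = 15L,
  lq_schema_error = 16L,
  lq_format_error = 17L
)
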