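#' Pipeline configuration
#'
#' All tunables of the detection and quantification pipeline in one
#' validated object. Unknown keys are rejected.
#'
#' @param median_radius_px Median filter radius (pixels).
#' @param binarize_method `"otsu"` or `"fixed"`.
#' @param binarize_threshold Threshold for `"fixed"` binarization.
#' @param morphology_radius_px Opening disc radius for fibre extraction.
#' @param min_area_px,min_circularity Fibre region filters.
#' @param dilation_radius_px Dilation radius locating the inter-fibre band.
#' @param refine_band Intersect the dilation band with the bright membrane
#'   mask so ellipse size tracks the actual membrane thickness (default
#'   TRUE).
#' @param semi_major_px,semi_minor_px,spacing_px Ellipse geometry; NULL
#'   derives them from the measured wall thickness.
#' @param weights Ranking weights (brightness, orientation, wall overlap).
#' @param n_rois ROIs selected per field (default 26).
#' @param fields_per_biopsy Fields per biopsy (default 3).
#' @param peak_policy `"per_biopsy"` (single emission peak per biopsy from
#'   the pooled mean spectrum) or `"per_field"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(median_radius_px = 1L,
                            binarize_method = c("otsu", "fixed"),
                            binarize_threshold = NULL,
                            morphology_radius_px = 2L,
                            min_area_px = 300L,
                            min_circularity = 0.3,
                            dilation_radius_px = 4L,
                            refine_band = TRUE,
                            semi_major_px = NULL,
                            semi_minor_px = NULL,
                            spacing_px = NULL,
                            weights = c(1, 1, 1) / 3,
                            n_rois = 26L,
                            fields_per_biopsy = 3L,
                            peak_policy = c("per_biopsy", "per_field")) {
  cfg <- list(median_radius_px = median_radius_px,
              binarize_method = match.arg(binarize_method),
              binarize_threshold = binarize_threshold,
              morphology_radius_px = morphology_radius_px,
              min_area_px = min_area_px,
              min_circularity = min_circularity,
              dilation_radius_px = dilation_radius_px,
              refine_band = isTRUE(refine_band),
              semi_major_px = semi_major_px,
              semi_minor_px = semi_minor_px,
              spacing_px = spacing_px,
              weights = weights,
              n_rois = n_rois,
              fields_per_biopsy = fields_per_biopsy,
              peak_policy = match.arg(peak_policy))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is_count(cfg$median_radius_px, 1) || !is_count(cfg$morphology_radius_px, 1) ||
      !is_count(cfg$dilation_radius_px, 1) || !is_count(cfg$n_rois, 1) ||
      !is_count(cfg$fields_per_biopsy, 1) || !is_count(cfg$min_area_px, 1))
    stop_dq("pipeline radii and counts must be positive integers",
            class = "dq_config_error")
  if (cfg$min_circularity < 0 || cfg$min_circularity > 1.1)
    stop_dq("min_circularity must lie in [0, 1.1]", class = "dq_config_error")
  if (length(cfg$weights) != 3 || any(cfg$weights < 0) ||
      abs(sum(cfg$weights) - 1) > 1e-8)
    stop_dq("weights must be 3 non-negative values summing to 1",
            class = "dq_config_error")
  structure(cfg, class = "pipeline_config")
}

#' Update a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param updates Named list of fields to replace; unknown keys are an error.
#' @return The updated, re-validated configuration.
#' @export
update_config <- function(config, updates) {
  if (!inherits(config, "pipeline_config"))
    stop_dq("config must be a pipeline_config", class = "dq_config_error")
  unknown <- setdiff(names(updates), names(config))
  if (length(unknown))
    stop_dq("unknown configuration key(s): ", paste(unknown, collapse = ", "),
            class = "dq_config_error")
  cfg <- unclass(config)
  for (k in names(updates)) cfg[[k]] <- updates[[k]]
  if (is.character(cfg$binarize_method))
    cfg$binarize_method <- match.arg(cfg$binarize_method, c("otsu", "fixed"))
  if (is.character(cfg$peak_policy))
    cfg$peak_policy <- match.arg(cfg$peak_policy, c("per_biopsy", "per_field"))
  validate_config(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k,
                if (is.null(v)) "auto" else paste(format(v, digits = 4), collapse = " ")))
  }
  invisible(x)
}
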