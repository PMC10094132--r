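#' Mean emission spectrum of an ROI (spectral signature)
#'
#' The spectral signature of an ROI is the arithmetic mean intensity of its
#' member pixels in every wavelength window. Rasterization is
#' pixel-center-inside-ellipse, identical to the overlap tests of the
#' selection stage.
#'
#' @param stack A [spectral_stack()].
#' @param roi One-row ROI data frame.
#' @return Object of class `spectrum`: `axis` and `values` (one mean per
#'   window).
#' @export
roi_mean_spectrum <- function(stack, roi) {
  d <- dim(stack$cube)
  px <- roi_pixels(validate_rois(roi), d[1:2])
  plane <- d[1] * d[2]
  values <- vapply(seq_len(d[3]), function(k)
    mean(stack$cube[px$idx + (k - 1L) * plane]), numeric(1))
  structure(list(axis = stack$axis, values = values), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  k <- which.max(x$values)
  cat(sprintf("<spectrum> %d windows; peak %.1f a.u. at %.2f nm\n",
              length(x$values), x$values[k], x$axis$centers_nm[k]))
  invisible(x)
}

#' Maximum-emission-peak window of a set of spectra
#'
#' Averages the spectra element-wise and returns the window center with the
#' maximal average (ties towards the lowest wavelength). Reading every ROI at
#' this single shared window is what turns a spectral signature into the
#' study's single intensity value per ROI.
#'
#' @param spectra List of `spectrum` objects sharing one axis.
#' @return List with `peak_center_nm` and `peak_index`.
#' @export
peak_wavelength <- function(spectra) {
  if (length(spectra) < 1L)
    stop_dq("need at least one spectrum", class = "dq_empty_input_error")
  ax <- spectra[[1]]$axis
  for (s in spectra) if (!axes_equal(s$axis, ax))
    stop_dq("spectra do not share a wavelength axis", class = "dq_axis_error")
  avg <- rowMeans(vapply(spectra, function(s) s$values,
                         numeric(length(ax$centers_nm))))
  k <- which.max(avg)
  list(peak_center_nm = ax$centers_nm[k], peak_index = k)
}

#' Quantify one field: per-ROI spectra and peak intensities
#'
#' Computes the spectral signature of every ROI, selects the field's
#' emission-peak window from the average of those signatures, and reads each
#' ROI's intensity at that window.
#'
#' @param stack The channel to quantify (typically a dystrophin stack).
#' @param rois A `roi_set` or ROI data frame.
#' @param field_id Identifier stored on the result.
#' @return Object of class `field_quant`: `field_id`, `spectra`,
#'   `peak_center_nm`, `peak_index`, `intensities`.
#' @export
quantify_field <- function(stack, rois, field_id = NULL) {
  if (inherits(rois, "roi_set")) {
    field_id <- field_id %||% rois$field_id
    rois <- rois$rois
  }
  if (nrow(rois) < 1L)
    stop_dq("empty ROI set", class = "dq_empty_input_error")
  spectra <- lapply(seq_len(nrow(rois)), function(i)
    roi_mean_spectrum(stack, rois[i, ]))
  pk <- peak_wavelength(spectra)
  structure(list(field_id = field_id %||% "", spectra = spectra,
                 peak_center_nm = pk$peak_center_nm,
                 peak_index = pk$peak_index,
                 intensities = vapply(spectra, function(s)
                   s$values[pk$peak_index], numeric(1))),
            class = "field_quant")
}

#' @export
print.field_quant <- function(x, ...) {
  cat(sprintf("<field_quant> field '%s': %d ROIs, peak %.2f nm, mean %.1f a.u.\n",
              x$field_id, length(x$intensities), x$peak_center_nm,
              mean(x$intensities)))
  invisible(x)
}

#' Aggregate field quantifications into a biopsy result
#'
#' With the default `per_biopsy` policy the emission peak is re-selected
#' from the pooled mean spectrum of all ROIs across the biopsy's fields and
#' every ROI re-read at that single window; `per_field` keeps each field's
#' own peak. The summary is the mean and standard error over all pooled
#' ROIs.
#'
#' @param fields List of [quantify_field()] results.
#' @param biopsy_id,group_label,antibody_label Identifiers for the output.
#' @param peak_policy `"per_biopsy"` or `"per_field"`.
#' @return Object of class `biopsy_result`.
#' @export
aggregate_biopsy <- function(fields, biopsy_id = "", group_label = "",
                             antibody_label = "",
                             peak_policy = c("per_biopsy", "per_field")) {
  peak_policy <- match.arg(peak_policy)
  if (length(fields) < 1L)
    stop_dq("need at least one field", class = "dq_empty_input_error")
  if (peak_policy == "per_biopsy") {
    spectra <- do.call(c, lapply(fields, function(f) f$spectra))
    pk <- peak_wavelength(spectra)
    values <- vapply(spectra, function(s) s$values[pk$peak_index], numeric(1))
    peak_nm <- pk$peak_center_nm
  } else {
    values <- unlist(lapply(fields, function(f) f$intensities))
    peak_nm <- NA_real_
  }
  n <- length(values)
  field_ids <- vapply(fields, function(f) f$field_id, character(1))
  structure(list(biopsy_id = biopsy_id, group_label = group_label,
                 antibody_label = antibody_label, n_rois = n,
                 mean_intensity = mean(values),
                 se_intensity = stats::sd(values) / sqrt(n),
                 peak_center_nm = peak_nm, peak_policy = peak_policy,
                 roi_values = values, field_ids = field_ids),
            class = "biopsy_result")
}

#' @export
print.biopsy_result <- function(x, ...) {
  cat(sprintf("<biopsy_result> %s (%s, %s): %.1f +/- %.1f a.u. over %d ROIs (peak policy %s)\n",
              x$biopsy_id, x$group_label, x$antibody_label,
              x$mean_intensity, x$se_intensity, x$n_rois, x$peak_policy))
  invisible(x)
}

#' Signal as a percentage of a reference mean
#'
#' Expresses a measured intensity as a percentage of a reference (e.g. a
#' residual dystrophin signal relative to the healthy-control mean),
#' reported to one decimal.
#'
#' @param signal_au Measured intensity (a.u.).
#' @param reference_mean_au Reference mean intensity (a.u., > 0).
#' @return Percentage, rounded to one decimal.
#' @examples
#' detection_percentage(15, 2982.9)  # 0.5
#' @export
detection_percentage <- function(signal_au, reference_mean_au) {
  if (!is.numeric(reference_mean_au) || reference_mean_au <= 0)
    stop_dq("reference_mean_au must be positive", class = "dq_parameter_error")
  round(100 * signal_au / reference_mean_au, 1)
}
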