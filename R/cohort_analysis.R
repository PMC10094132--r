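#' Simulate and quantify a whole cohort, streaming field by field
#'
#' Materializes each synthetic field in turn (so only one field's image
#' cubes are in memory at a time), detects ROIs automatically on the
#' beta-spectrin channel and/or places oracle "manual" ROIs from ground
#' truth, quantifies every dystrophin antibody channel with each ROI mode,
#' and aggregates to biopsy results.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param modes Character subset of `c("auto", "oracle")`.
#' @param config A [pipeline_config()].
#' @param quantify_beta Also quantify the beta-spectrin channel (diagnostic
#'   output; beta-spectrin is never used to normalize dystrophin).
#' @param progress Print one line per biopsy.
#' @return Object of class `cohort_result`: `biopsy_summaries` (data frame:
#'   biopsy_id, group, antibody, mode, n_rois, mean_intensity, se_intensity,
#'   peak_center_nm, true_mean), `roi_values` (long data frame of per-ROI
#'   peak intensities) and `mean_spectra` (long data frame of per-biopsy
#'   pooled mean spectra).
#' @export
quantify_cohort <- function(spec = cohort_spec(), seed = 1L,
                            modes = c("auto", "oracle"),
                            config = pipeline_config(),
                            quantify_beta = FALSE, progress = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  plan <- cohort_plan(spec, seed)
  summaries <- list(); roi_rows <- list(); spec_rows <- list()
  for (b in plan$biopsies) {
    # per antibody x mode: list of field_quant objects
    channels <- c(spec$antibodies, if (quantify_beta) "beta-spectrin")
    fq <- list()
    for (fi in seq_len(spec$fields_per_biopsy)) {
      fld <- build_field(plan, b$biopsy_id, fi)
      field_id <- sprintf("%s_f%d", b$biopsy_id, fi)
      roisets <- list()
      if ("auto" %in% modes)
        roisets$auto <- detect_rois(fld$beta_stack, config, field_id)
      if ("oracle" %in% modes)
        roisets$oracle <- oracle_rois(fld$geometry, n = config$n_rois,
                                      seed = b$geom_seeds[fi] %% 1000000L + 1L)
      for (mode in names(roisets)) {
        for (ch in channels) {
          stk <- if (ch == "beta-spectrin") fld$beta_stack else fld$dys_stacks[[ch]]
          key <- paste(ch, mode, sep = "|")
          fq[[key]] <- c(fq[[key]], list(quantify_field(stk, roisets[[mode]],
                                                        field_id)))
        }
      }
      rm(fld)
    }
    for (key in names(fq)) {
      ch <- sub("\\|.*$", "", key); mode <- sub("^.*\\|", "", key)
      res <- aggregate_biopsy(fq[[key]], b$biopsy_id, b$group, ch,
                              peak_policy = config$peak_policy)
      summaries[[length(summaries) + 1L]] <- data.frame(
        biopsy_id = b$biopsy_id, group = b$group, antibody = ch, mode = mode,
        n_rois = res$n_rois, mean_intensity = res$mean_intensity,
        se_intensity = res$se_intensity, peak_center_nm = res$peak_center_nm,
        true_mean = unname(b$true_means[[ch]]))
      roi_rows[[length(roi_rows) + 1L]] <- data.frame(
        biopsy_id = b$biopsy_id, group = b$group, antibody = ch, mode = mode,
        roi = seq_along(res$roi_values), value = res$roi_values)
      pooled <- do.call(c, lapply(fq[[key]], function(f) f$spectra))
      avg <- rowMeans(vapply(pooled, function(s) s$values,
                             numeric(length(pooled[[1]]$values))))
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        biopsy_id = b$biopsy_id, group = b$group, antibody = ch, mode = mode,
        center_nm = pooled[[1]]$axis$centers_nm, mean_value = avg)
    }
    if (progress)
      message("quantified ", b$biopsy_id, " (", spec$fields_per_biopsy, " fields)")
  }
  structure(list(biopsy_summaries = do.call(rbind, summaries),
                 roi_values = do.call(rbind, roi_rows),
                 mean_spectra = do.call(rbind, spec_rows),
                 spec = spec, seed = seed, modes = modes),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  s <- x$biopsy_summaries
  cat(sprintf("<cohort_result> %d biopsies, antibodies: %s, modes: %s\n",
              length(unique(s$biopsy_id)),
              paste(unique(s$antibody), collapse = ", "),
              paste(unique(s$mode), collapse = ", ")))
  invisible(x)
}

#' Group-level statistics of a cohort result
#'
#' Pools per-ROI peak intensities per group (as in the study's group
#' summaries over all patients' ROIs) and runs [compare_groups()] for each
#' antibody; when both ROI modes are present, adds the manual-vs-automatic
#' [compare_methods()] equal-variance t-test on per-biopsy means.
#'
#' @param result A [quantify_cohort()] result.
#' @param mode ROI mode used for group comparisons (default `"auto"` if
#'   present).
#' @return List with per-antibody `group_tests` and (optionally)
#'   `method_tests`.
#' @export
cohort_statistics <- function(result, mode = NULL) {
  s <- result$biopsy_summaries
  rv <- result$roi_values
  mode <- mode %||% if ("auto" %in% s$mode) "auto" else s$mode[1]
  abs_ <- setdiff(unique(s$antibody), "beta-spectrin")
  group_tests <- lapply(abs_, function(ab) {
    sub <- rv[rv$antibody == ab & rv$mode == mode, ]
    vals <- split(sub$value, sub$group)
    if (length(vals) >= 2 && all(lengths(vals) >= 3)) compare_groups(vals) else NULL
  })
  names(group_tests) <- abs_
  method_tests <- NULL
  if (all(c("auto", "oracle") %in% unique(s$mode))) {
    method_tests <- lapply(abs_, function(ab) {
      man <- s$mean_intensity[s$antibody == ab & s$mode == "oracle"]
      aut <- s$mean_intensity[s$antibody == ab & s$mode == "auto"]
      compare_methods(man, aut)
    })
    names(method_tests) <- abs_
  }
  list(group_tests = group_tests, method_tests = method_tests, mode = mode)
}
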