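#' Reference fluorescence levels used as simulation defaults
#'
#' Published group-level sarcolemmal mean fluorescence intensities (a.u. on
#' the 12-bit scale) and their standard errors over 78 pooled ROIs, for the
#' three dystrophin antibodies (NCL-Dys1 rod domain, NCL-Dys2 C-terminal,
#' NCL-Dys3 N-terminal) and the beta-spectrin membrane guide, in DMD, BMD and
#' healthy-control muscle. The simulator uses `mean_au` as the group wall
#' mean and `roi_sd_au` as the between-ROI standard deviation; for the
#' dystrophin antibodies `roi_sd_au = se_au * sqrt(78)` (the printed errors
#' are standard errors of 78 pooled ROIs), while for beta-spectrin, whose
#' printed errors pool at an unstated level, a 15% coefficient of variation
#' is assumed instead.
#'
#' @return A data frame with columns `group`, `antibody`, `mean_au`, `se_au`,
#'   `roi_sd_au`.
#' @export
reference_levels <- function() {
  df <- data.frame(
    group = rep(c("DMD", "BMD", "CONTROL"), each = 4),
    antibody = rep(c("NCL-Dys1", "NCL-Dys2", "NCL-Dys3", "beta-spectrin"), 3),
    mean_au = c(500.8, 590.7, 296.8, 2346.13,
                1190.8, 1219.7, 526.02, 2379.38,
                2982.9, 2732.214, 2920.4, 1832.17),
    se_au = c(17.6, 25.3, 7.35, 65.88,
              42.1, 44.56, 17.13, 62.43,
              29.3, 28.4, 30.91, 132.30))
  df$roi_sd_au <- ifelse(df$antibody == "beta-spectrin",
                         0.15 * df$mean_au, df$se_au * sqrt(78))
  df
}

# Default group_intensity_params for one group x antibody cell, optionally
# recentered on a biopsy-specific wall mean.
params_for <- function(group, antibody, wall_mean = NULL, noise = NULL) {
  lv <- reference_levels()
  row <- lv[lv$group == group & lv$antibody == antibody, ]
  if (nrow(row) != 1L)
    stop_dq("no reference level for ", group, " / ", antibody,
            class = "dq_parameter_error")
  noise <- noise %||% list(readout_sd = 10, shot_scale = 2)
  group_intensity_params(group, wall_mean = wall_mean %||% row$mean_au,
                         wall_sd = row$roi_sd_au,
                         readout_sd = noise$readout_sd,
                         shot_scale = noise$shot_scale)
}

#' Cohort specification for the simulator
#'
#' Defaults mirror the study design: 10 DMD, 3 BMD and 6 control biopsies,
#' three 512 x 512 fields per biopsy, ~30 fibres per field with a 4 px
#' (~1.4 um) sarcolemma wall, quantified with the NCL-Dys1 antibody. Biopsy
#' wall means are drawn around the group mean with a between-biopsy
#' coefficient of variation `between_biopsy_cv` (0 makes all biopsies of a
#' group identical in truth).
#'
#' @param groups Data frame with columns `group` (DMD/BMD/CONTROL) and
#'   `n_biopsies`.
#' @param fields_per_biopsy Fields imaged per biopsy (default 3).
#' @param antibodies Character vector of dystrophin antibody labels to
#'   render (subset of the [reference_levels()] antibodies).
#' @param rows,cols,n_fibres,wall_thickness_px Field geometry parameters.
#' @param between_biopsy_cv Between-biopsy coefficient of variation of the
#'   true wall mean.
#' @param noise List with `readout_sd` and `shot_scale` (set both 0 for
#'   noiseless fields).
#' @param confounder_fracs Passed to [generate_geometry()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = data.frame(group = c("DMD", "BMD", "CONTROL"),
                                            n_biopsies = c(10L, 3L, 6L)),
                        fields_per_biopsy = 3L,
                        antibodies = "NCL-Dys1",
                        rows = 512L, cols = 512L, n_fibres = 30L,
                        wall_thickness_px = 4L,
                        between_biopsy_cv = 0.05,
                        noise = list(readout_sd = 10, shot_scale = 2),
                        confounder_fracs = NULL) {
  if (!is.data.frame(groups) || nrow(groups) < 1L ||
      !all(c("group", "n_biopsies") %in% names(groups)))
    stop_dq("groups must be a non-empty data frame with group and n_biopsies",
            class = "dq_parameter_error")
  if (!all(groups$group %in% c("DMD", "BMD", "CONTROL")))
    stop_dq("unknown group label(s): ",
            paste(setdiff(groups$group, c("DMD", "BMD", "CONTROL")), collapse = ", "),
            class = "dq_parameter_error")
  if (any(groups$n_biopsies < 1))
    stop_dq("each group needs n_biopsies >= 1", class = "dq_parameter_error")
  known_ab <- setdiff(unique(reference_levels()$antibody), "beta-spectrin")
  if (!all(antibodies %in% known_ab))
    stop_dq("unknown antibody label(s): ",
            paste(setdiff(antibodies, known_ab), collapse = ", "),
            class = "dq_parameter_error")
  structure(list(groups = groups, fields_per_biopsy = as.integer(fields_per_biopsy),
                 antibodies = antibodies, rows = as.integer(rows),
                 cols = as.integer(cols), n_fibres = as.integer(n_fibres),
                 wall_thickness_px = as.integer(wall_thickness_px),
                 between_biopsy_cv = between_biopsy_cv, noise = noise,
                 confounder_fracs = confounder_fracs),
            class = "cohort_spec")
}

# Deterministic per-biopsy truth and per-field seeds for a cohort.
cohort_plan <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    biopsies <- list()
    for (gi in seq_len(nrow(spec$groups))) {
      g <- spec$groups$group[gi]
      for (b in seq_len(spec$groups$n_biopsies[gi])) {
        id <- sprintf("%s_%02d", g, b)
        lv <- reference_levels()
        means <- sapply(c(spec$antibodies, "beta-spectrin"), function(ab) {
          mu <- lv$mean_au[lv$group == g & lv$antibody == ab]
          pmax(0, rnorm(1, mu, spec$between_biopsy_cv * mu))
        })
        fseeds <- sample.int(.Machine$integer.max - 1L, 2L * spec$fields_per_biopsy)
        biopsies[[id]] <- list(biopsy_id = id, group = g, true_means = means,
                               geom_seeds = fseeds[seq_len(spec$fields_per_biopsy)],
                               render_seeds = fseeds[-seq_len(spec$fields_per_biopsy)])
      }
    }
    list(spec = spec, seed = seed, biopsies = biopsies)
  })
}

# Materialize one field of one biopsy from a plan.
build_field <- function(plan, biopsy_id, field_index) {
  spec <- plan$spec
  b <- plan$biopsies[[biopsy_id]]
  geom <- generate_geometry(spec$rows, spec$cols, spec$n_fibres,
                            spec$wall_thickness_px, spec$confounder_fracs,
                            seed = b$geom_seeds[field_index])
  dys_params <- lapply(spec$antibodies, function(ab)
    params_for(b$group, ab, wall_mean = b$true_means[[ab]], noise = spec$noise))
  names(dys_params) <- spec$antibodies
  beta_params <- params_for(b$group, "beta-spectrin",
                            wall_mean = b$true_means[["beta-spectrin"]],
                            noise = spec$noise)
  render_field(geom, beta_params, dys_params,
               seed = b$render_seeds[field_index])
}

#' Generate a synthetic cohort of spectral fields
#'
#' Materializes every field of every biopsy in `spec` (deterministically for
#' a fixed seed). For large cohorts this holds many image cubes in memory;
#' prefer [quantify_cohort()] which streams field by field.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List of biopsies, each a list with `biopsy_id`, `group`,
#'   `true_means` and `fields` (list of `synthetic_field`s).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  plan <- cohort_plan(spec, seed)
  lapply(plan$biopsies, function(b) {
    fields <- lapply(seq_len(spec$fields_per_biopsy), function(fi)
      build_field(plan, b$biopsy_id, fi))
    list(biopsy_id = b$biopsy_id, group = b$group,
         true_means = b$true_means, fields = fields)
  })
}

#' Simulate a single biopsy at a fixed true wall intensity
#'
#' Convenience wrapper used for parameter-recovery checks: renders
#' `n_fields` fields of one biopsy whose true sarcolemma peak intensity is
#' exactly `wall_mean` (no between-biopsy variation).
#'
#' @param group Group label.
#' @param antibody Dystrophin antibody label.
#' @param wall_mean True wall mean (a.u.); defaults to the group's
#'   [reference_levels()] entry.
#' @param n_fields Number of fields.
#' @param seed Integer seed.
#' @param ... Passed to [cohort_spec()] (e.g. `rows`, `n_fibres`, `noise`).
#' @return A list of `synthetic_field`s.
#' @export
simulate_biopsy <- function(group, antibody = "NCL-Dys1", wall_mean = NULL,
                            n_fields = 3L, seed = 1L, ...) {
  spec <- cohort_spec(groups = data.frame(group = group, n_biopsies = 1L),
                      fields_per_biopsy = n_fields, antibodies = antibody,
                      between_biopsy_cv = 0, ...)
  plan <- cohort_plan(spec, seed)
  b <- plan$biopsies[[1]]
  if (!is.null(wall_mean)) b$true_means[[antibody]] <- wall_mean
  plan$biopsies[[1]] <- b
  lapply(seq_len(n_fields), function(fi) build_field(plan, b$biopsy_id, fi))
}

#' Simulate one default synthetic field
#'
#' One field of a biopsy of the given group at the reference intensity
#' levels; the package-wide "default field" used in examples and checks is a
#' DMD field at 512 x 512 with ~30 fibres and a 4 px wall.
#'
#' @inheritParams simulate_biopsy
#' @export
simulate_field <- function(group = "DMD", antibody = "NCL-Dys1", seed = 1L, ...) {
  simulate_biopsy(group, antibody, n_fields = 1L, seed = seed, ...)[[1]]
}

#' Oracle "manual" membrane ROIs from ground truth
#'
#' Stands in for the human operator of the manual protocol: places `n`
#' non-overlapping ellipses centered on the ground-truth wall midline, major
#' axis aligned with the local wall tangent, each with at least 90% of its
#' pixels on the sarcolemma.
#'
#' @param geometry A [generate_geometry()] result with a non-empty wall.
#' @param n Number of ROIs (default 26 per field).
#' @param semi_major_px,semi_minor_px Ellipse semi-axes; default from the
#'   wall thickness (`semi_minor = max(1, t/2 - 0.5)`, `semi_major = 2 *
#'   semi_minor`).
#' @param seed Integer seed for the placement order.
#' @return ROI data frame with `n` rows.
#' @export
oracle_rois <- function(geometry, n = 26L, semi_major_px = NULL,
                        semi_minor_px = NULL, seed = 1L) {
  g <- geometry
  if (!any(g$wall_mask))
    stop_dq("geometry has an empty wall mask", class = "dq_parameter_error")
  semi_minor_px <- semi_minor_px %||% max(1, g$wall_thickness_px / 2 - 0.5)
  semi_major_px <- semi_major_px %||% (2 * semi_minor_px)
  cand <- which(g$wall_midline)
  R <- g$rows
  rows0 <- (cand - 1L) %% R          # 0-based
  cols0 <- (cand - 1L) %/% R
  with_seed(seed, {
    ord <- sample.int(length(cand))
    occupied <- logical(R * g$cols)
    out <- vector("list", n)
    got <- 0L
    for (j in ord) {
      roi <- data.frame(center_row = rows0[j], center_col = cols0[j],
                        semi_major = semi_major_px, semi_minor = semi_minor_px,
                        theta = g$wall_tangent[cand[j]] %% pi)
      px <- tryCatch(roi_pixels(roi, c(R, g$cols)), error = function(e) NULL)
      if (is.null(px)) next
      if (mean(g$wall_mask[px$idx]) < 0.9) next
      if (any(occupied[px$idx])) next
      occupied[px$idx] <- TRUE
      got <- got + 1L
      out[[got]] <- roi
      if (got == n) break
    }
    if (got < n)
      stop_dq("could only place ", got, " of ", n,
              " non-overlapping membrane ROIs", class = "dq_placement_error")
    do.call(rbind, out[seq_len(got)])
  })
}
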