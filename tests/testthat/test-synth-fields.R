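# Synthetic muscle-field generator: geometry, rendering, cohorts and oracle
# membrane ROIs.

test_that("geometry is deterministic and internally consistent", {
  g1 <- tiny_geometry(seed = 1)
  g2 <- tiny_geometry(seed = 1)
  expect_identical(g1$label_image, g2$label_image)
  expect_identical(g1$wall_patch, g2$wall_patch)

  expect_gt(sum(g1$wall_mask), 0)
  expect_false(any(g1$wall_mask & g1$label_image > 0))   # wall vs interiors
  expect_gte(g1$fibre_count, 1L)
  expect_true(all(!is.na(g1$wall_tangent[g1$wall_mask])))
  expect_true(all(g1$wall_patch[g1$wall_mask] >= 1L))

  g3 <- tiny_geometry(seed = 2)
  expect_false(identical(g1$label_image, g3$label_image))
})

test_that("mean fibre equivalent diameter matches the frame-derived value", {
  g <- generate_geometry(256, 256, 12, 4, seed = 3)
  areas <- tabulate(g$label_image[g$label_image > 0])
  mean_eqd <- mean(sqrt(4 * areas / pi))
  frame_eqd <- sqrt(4 * (256 * 256) / (pi * 12))
  # fibres lose area to walls, so the observed diameter sits slightly below
  expect_lt(abs(mean_eqd - frame_eqd) / frame_eqd, 0.25)
  expect_gt(mean_eqd, 0.6 * frame_eqd)
})

test_that("confounder cells are placed without destroying the field", {
  g <- tiny_geometry(seed = 5, n_fibres = 15L,
                     confounder_fracs = c(vessel = 0.03, adipose = 0.03,
                                          connective = 0.03))
  expect_true(any(g$label_image == -2L))
  expect_true(any(g$label_image == -3L))
  expect_true(any(g$label_image == -4L))
  expect_gte(g$fibre_count, ceiling(0.8 * 15))
  expect_error(tiny_geometry(seed = 5, n_fibres = 15L,
                             confounder_fracs = c(vessel = 0.9)),
               class = "dq_parameter_error")
  expect_error(tiny_geometry(confounder_fracs = c(nucleus = 0.1)),
               class = "dq_parameter_error")
  expect_error(generate_geometry(64, 64, 500, 4, seed = 1),
               class = "dq_parameter_error")
})

test_that("rendering is seeded-deterministic and respects the 12-bit ceiling", {
  g <- tiny_geometry(seed = 2)
  p <- group_intensity_params("DMD", wall_mean = 3000, wall_sd = 150)
  f1 <- render_field(g, p, p, seed = 7)
  f2 <- render_field(g, p, p, seed = 7)
  expect_identical(f1$dys_stack$cube, f2$dys_stack$cube)
  expect_identical(f1$beta_stack$cube, f2$beta_stack$cube)
  f3 <- render_field(g, p, p, seed = 8)
  expect_false(identical(f1$dys_stack$cube, f3$dys_stack$cube))

  expect_lte(max(f1$dys_stack$cube), 4095)
  expect_lte(max(f1$beta_stack$cube), 4095)
  expect_gte(min(f1$dys_stack$cube), 0)

  # a wall mean far above the ceiling must be flagged as clipping
  pc <- group_intensity_params("DMD", wall_mean = 6000, wall_sd = 0)
  fc <- render_field(g, p, pc, seed = 7)
  expect_true(fc$truth$dys[[1]]$clipping_warning)
  expect_false(f1$truth$dys[[1]]$clipping_warning)
})

test_that("rendered wall intensity recovers the generating wall mean", {
  g <- tiny_geometry(seed = 3)
  # wall_sd = 0 so the only wall-pixel scatter is observation noise
  p <- group_intensity_params("CONTROL", wall_mean = 2000, wall_sd = 0)
  f <- render_field(g, p, p, seed = 1)
  peak_k <- f$truth$dys[[1]]$peak_slice
  wall_vals <- f$dys_stack$cube[, , peak_k][g$wall_mask]
  se <- sd(wall_vals) / sqrt(length(wall_vals))
  expect_lt(abs(mean(wall_vals) - 2000), 2 * se + 0.5)  # 0.5 for quantization

  # null signal: dystrophin-negative wall is indistinguishable from background
  p0 <- group_intensity_params("DMD", wall_mean = 0, wall_sd = 0,
                               readout_sd = 10, shot_scale = 2)
  f0 <- render_field(g, p, p0, seed = 2)
  wall0 <- f0$dys_stack$cube[, , peak_k][g$wall_mask]
  bg0 <- f0$dys_stack$cube[, , peak_k][g$label_image > 0]
  se0 <- sqrt(sd(wall0)^2 / length(wall0) + sd(bg0)^2 / length(bg0))
  expect_lt(abs(mean(wall0) - mean(bg0)), 3 * se0 + 0.5)
})

test_that("the spectral peak lands on the window nearest the emission peak", {
  g <- tiny_geometry(seed = 4)
  p <- group_intensity_params("BMD", wall_mean = 1500, wall_sd = 0,
                              readout_sd = 0, shot_scale = 0)
  f <- render_field(g, p, p, seed = 1)
  wall_spec <- vapply(seq_len(dim(f$dys_stack$cube)[3]), function(k)
    mean(f$dys_stack$cube[, , k][g$wall_mask]), numeric(1))
  ax <- f$dys_stack$axis$centers_nm
  expect_equal(which.max(wall_spec), which.min(abs(ax - 519)))
  bspec <- vapply(seq_len(dim(f$beta_stack$cube)[3]), function(k)
    mean(f$beta_stack$cube[, , k][g$wall_mask]), numeric(1))
  bax <- f$beta_stack$axis$centers_nm
  expect_equal(which.max(bspec), which.min(abs(bax - 670)))
})

test_that("wall intensity responds monotonically to the generating mean", {
  g <- tiny_geometry(seed = 6)
  means <- c(200, 800, 2400)
  rendered <- vapply(means, function(mu) {
    p <- group_intensity_params("DMD", wall_mean = mu, wall_sd = 0,
                                readout_sd = 0, shot_scale = 0)
    f <- render_field(g, p, p, seed = 3)
    mean(f$dys_stack$cube[, , f$truth$dys[[1]]$peak_slice][g$wall_mask])
  }, numeric(1))
  expect_true(all(diff(rendered) > 0))
})

test_that("bleed-through adds the other channel's signal when enabled", {
  g <- tiny_geometry(seed = 7)
  beta <- group_intensity_params("DMD", wall_mean = 2300, wall_sd = 0,
                                 readout_sd = 0, shot_scale = 0)
  dys0 <- group_intensity_params("DMD", wall_mean = 0, wall_sd = 0,
                                 readout_sd = 0, shot_scale = 0)
  clean <- render_field(g, beta, dys0, seed = 1)
  bled <- render_field(g, beta, dys0, seed = 1, bleed_beta_into_dys = 0.2)
  k <- dim(bled$dys_stack$cube)[3]   # reddest dystrophin window, nearest Cy5
  expect_gt(mean(bled$dys_stack$cube[, , k][g$wall_mask]),
            mean(clean$dys_stack$cube[, , k][g$wall_mask]))
})

test_that("cohorts have the study shape and deterministic truth", {
  spec <- cohort_spec(rows = 64L, cols = 64L, n_fibres = 4L)
  co <- generate_cohort(spec, seed = 1)
  expect_length(co, 10 + 3 + 6)
  expect_equal(sum(vapply(co, function(b) length(b$fields), integer(1))), 57L)
  groups <- vapply(co, function(b) b$group, character(1))
  expect_equal(unname(table(groups)[c("DMD", "BMD", "CONTROL")]),
               c(10L, 3L, 6L), ignore_attr = TRUE)

  # zero between-biopsy SD: every biopsy of a group shares the true mean
  spec0 <- cohort_spec(groups = data.frame(group = "BMD", n_biopsies = 3L),
                       rows = 64L, cols = 64L, n_fibres = 4L,
                       between_biopsy_cv = 0)
  co0 <- generate_cohort(spec0, seed = 2)
  mus <- unname(vapply(co0, function(b)
    unname(b$true_means[["NCL-Dys1"]]), numeric(1)))
  expect_equal(mus, rep(mus[1], 3))

  expect_error(cohort_spec(groups = data.frame(group = "DND", n_biopsies = 1)),
               class = "dq_parameter_error")
  expect_error(cohort_spec(groups = data.frame(group = character(0),
                                               n_biopsies = integer(0))),
               class = "dq_parameter_error")
})

test_that("oracle ROIs are membrane-only, non-overlapping and aligned", {
  g <- tiny_geometry(seed = 8)
  rois <- oracle_rois(g, n = 26, seed = 1)
  expect_equal(nrow(rois), 26L)
  px_list <- lapply(seq_len(26), function(i)
    dysquant::roi_pixels(rois[i, ], c(g$rows, g$cols)))
  overlap <- vapply(px_list, function(px) mean(g$wall_mask[px$idx]), numeric(1))
  expect_true(all(overlap >= 0.9))
  all_idx <- unlist(lapply(px_list, `[[`, "idx"))
  expect_equal(length(all_idx), length(unique(all_idx)))  # pairwise disjoint

  # single-fibre field still accommodates one ROI on its ring
  g1 <- generate_geometry(64, 64, 1, 4, seed = 2)
  r1 <- oracle_rois(g1, n = 1, seed = 1)
  expect_equal(nrow(r1), 1L)

  # too many requested ROIs -> placement error reporting the shortfall
  err <- tryCatch(oracle_rois(g1, n = 500, seed = 1), error = identity)
  expect_s3_class(err, "dq_placement_error")
  expect_match(conditionMessage(err), "of 500")
})

test_that("a beta-spectrin channel at the DMD level is recovered from oracle ROIs", {
  flds <- simulate_biopsy("DMD", n_fields = 2, seed = 31, rows = 192L,
                          cols = 192L, n_fibres = 10L)
  vals <- unlist(lapply(flds, function(f) {
    rois <- oracle_rois(f$geometry, 26, seed = f$seed)
    quantify_field(f$beta_stack, rois)$intensities
  }))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 2346.13), 3 * se)
})
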