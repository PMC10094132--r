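# Spectral quantification: ROI mean spectra, peak selection, field and
# biopsy aggregation, and the detection-percentage helper.

test_that("ROI mean spectra equal the brute-force pixel loop", {
  s <- const_stack(42)
  roi <- elliptical_roi(5, 5, 3, 2, 0.3)
  expect_equal(roi_mean_spectrum(s, roi)$values, rep(42, 5))

  # 1-pixel ROI returns that pixel's lambda vector
  cube <- withr::with_seed(1, array(sample(0:4095, 12 * 12 * 5, TRUE),
                                    c(12, 12, 5)))
  st <- spectral_stack(cube, small_axis(), 470)
  one <- elliptical_roi(4, 7, 0.6, 0.6, 0)
  expect_equal(roi_mean_spectrum(st, one)$values, cube[5, 8, ])

  for (seed in 1:3) {
    roi <- withr::with_seed(seed, elliptical_roi(runif(1, 4, 8), runif(1, 4, 8),
                                                 runif(1, 2, 3.5), runif(1, 1, 2),
                                                 runif(1, 0, pi)))
    got <- roi_mean_spectrum(st, roi)$values
    # independent oracle: loop over every pixel, test the ellipse inequality
    want <- sapply(1:5, function(k) {
      acc <- c(); ct <- cos(roi$theta); st_ <- sin(roi$theta)
      for (i in 1:12) for (j in 1:12) {
        dy <- (i - 1) - roi$center_row; dx <- (j - 1) - roi$center_col
        u <- (dx * ct + dy * st_) / roi$semi_major
        v <- (-dx * st_ + dy * ct) / roi$semi_minor
        if (u^2 + v^2 <= 1) acc <- c(acc, cube[i, j, k])
      }
      mean(acc)
    })
    expect_equal(got, want)
  }

  out <- elliptical_roi(1, 1, 5, 3, 0)
  expect_error(roi_mean_spectrum(st, out), class = "dq_roi_error")
})

test_that("the peak window maximizes the average spectrum", {
  ax <- small_axis(7)
  tri <- structure(list(axis = ax, values = c(1, 2, 3, 4, 5, 6, 2)),
                   class = "spectrum")
  pk <- peak_wavelength(list(tri))
  expect_equal(pk$peak_index, 6L)
  expect_equal(pk$peak_center_nm, ax$centers_nm[6])

  # the average can peak where neither spectrum does: (10,0,8)+(0,10,8) -> 8,5,8
  ax3 <- small_axis(3)
  a <- structure(list(axis = ax3, values = c(10, 0, 8)), class = "spectrum")
  b <- structure(list(axis = ax3, values = c(0, 10, 8)), class = "spectrum")
  pk3 <- peak_wavelength(list(a, b))
  expect_equal(pk3$peak_index, 3L)        # average (5, 5, 8) peaks at window 3
  # tie in the average: lowest wavelength wins
  tie <- structure(list(axis = ax3, values = c(8, 5, 8)), class = "spectrum")
  expect_equal(peak_wavelength(list(tie))$peak_index, 1L)
  expect_error(peak_wavelength(list(a, tri)), class = "dq_axis_error")
})

test_that("field quantification reads every ROI at the shared peak", {
  f <- tiny_field("BMD", seed = 26)
  rs <- detect_rois(f$beta_stack)
  fq <- quantify_field(f$dys_stack, rs)
  expect_length(fq$intensities, 26L)
  expect_equal(fq$intensities,
               vapply(fq$spectra, function(s) s$values[fq$peak_index],
                      numeric(1)))
  ax <- f$dys_stack$axis$centers_nm
  expect_equal(fq$peak_center_nm, ax[which.min(abs(ax - 519))])

  zero <- spectral_stack(array(0, dim(f$dys_stack$cube)), f$dys_stack$axis, 470)
  expect_equal(quantify_field(zero, rs)$intensities, rep(0, 26))
  expect_error(quantify_field(f$dys_stack, rs$rois[0, ]),
               class = "dq_empty_input_error")
})

test_that("biopsy aggregation pools 78 ROIs and re-selects the peak", {
  flds <- simulate_biopsy("BMD", n_fields = 3, seed = 27, rows = 160L,
                          cols = 160L, n_fibres = 8L)
  fqs <- lapply(seq_along(flds), function(i)
    quantify_field(flds[[i]]$dys_stack, detect_rois(flds[[i]]$beta_stack),
                   field_id = paste0("f", i)))
  res <- aggregate_biopsy(fqs, "b1", "BMD", "NCL-Dys1")
  expect_equal(res$n_rois, 78L)
  expect_equal(res$mean_intensity, mean(res$roi_values))
  expect_equal(res$se_intensity, sd(res$roi_values) / sqrt(78))
  expect_equal(res$field_ids, c("f1", "f2", "f3"))

  pf <- aggregate_biopsy(fqs, "b1", "BMD", "NCL-Dys1", peak_policy = "per_field")
  expect_equal(pf$roi_values, unlist(lapply(fqs, `[[`, "intensities")),
               ignore_attr = TRUE)

  # constant values: mean c, SE 0
  cst <- lapply(1:2, function(i) quantify_field(const_stack(17),
                                                elliptical_roi(5, 5, 3, 2, 0)))
  agg <- aggregate_biopsy(cst)
  expect_equal(agg$mean_intensity, 17)
  expect_equal(agg$se_intensity, 0)
  expect_error(aggregate_biopsy(list()), class = "dq_empty_input_error")
})

test_that("quantification is linear under intensity scaling", {
  f <- tiny_field("DMD", seed = 28)
  rs <- detect_rois(f$beta_stack)
  fq1 <- quantify_field(f$dys_stack, rs)
  scaled <- f$dys_stack
  scaled$cube <- scaled$cube * 2
  scaled$cube[scaled$cube > 4095] <- 4095   # stays below with DMD levels
  expect_lt(max(f$dys_stack$cube) * 2, 4096)
  fq2 <- quantify_field(scaled, rs)
  expect_equal(fq2$peak_index, fq1$peak_index)
  expect_equal(fq2$intensities, 2 * fq1$intensities)
  expect_equal(mean(fq2$intensities), 2 * mean(fq1$intensities))
})

test_that("sub-percent residual signal is detectable above a null field", {
  g <- tiny_geometry(seed = 29)
  p15 <- group_intensity_params("DMD", wall_mean = 15, wall_sd = 2)
  p0 <- group_intensity_params("DMD", wall_mean = 0, wall_sd = 0)
  beta <- group_intensity_params("DMD", wall_mean = 2346, wall_sd = 300)
  f15 <- render_field(g, beta, p15, seed = 1)
  f0 <- render_field(g, beta, p0, seed = 2)
  rois <- oracle_rois(g, 26, seed = 3)
  v15 <- quantify_field(f15$dys_stack, rois)$intensities
  v0 <- quantify_field(f0$dys_stack, rois)$intensities
  tt <- t.test(v15, v0, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("detection percentage reproduces the worked residual-dystrophin case", {
  expect_equal(detection_percentage(15, 2982.9), 0.5)
  expect_equal(detection_percentage(123.4, 123.4), 100)
  expect_equal(detection_percentage(0, 500), 0)
  expect_error(detection_percentage(10, 0), class = "dq_parameter_error")
})
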