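# Sarcolemma location, ellipse proposal, scoring and top-n selection.

regions_from_mask <- function(m, ...) {
  extract_fibre_regions(m, min_area_px = 10, min_circularity = 0.1,
                        morphology_radius_px = 1, ...)
}

disc_mask2 <- function(nr, nc, cx, cy, r) {
  rows <- matrix(1:nr, nr, nc); cols <- matrix(1:nc, nr, nc, byrow = TRUE)
  (rows - cx)^2 + (cols - cy)^2 <= r^2
}

test_that("the sarcolemma band fills the gap between dilated fibres", {
  m <- disc_mask2(80, 80, 40, 25, 12) | disc_mask2(80, 80, 40, 55, 12)
  # discs are 6 px apart edge to edge (centers 30 apart, radius 12)
  reg <- regions_from_mask(m)
  sarc <- locate_sarcolemma(reg, c(80, 80), dilation_radius_px = 4)
  gap <- !m & disc_mask2(80, 80, 40, 25, 16) & disc_mask2(80, 80, 40, 55, 16)
  expect_gt(mean(sarc$mask[gap]), 0.95)   # the inter-disc band is covered
  expect_false(any(sarc$mask & reg$labels > 0))

  one <- regions_from_mask(disc_mask2(80, 80, 40, 40, 15))
  ann <- locate_sarcolemma(one, c(80, 80), dilation_radius_px = 4)
  area <- sum(ann$mask)
  expect_lt(abs(area - (pi * (19^2 - 15^2))) / area, 0.15)  # annulus width ~4
  expect_equal(ann$thickness_px, 4, tolerance = 1.1)

  empty <- regions_from_mask(matrix(FALSE, 40, 40))
  expect_error(locate_sarcolemma(empty, c(40, 40)),
               class = "dq_empty_input_error")
})

test_that("sarcolemma of a synthetic field matches ground truth", {
  f <- tiny_field("DMD", seed = 23, noiseless = TRUE)
  g <- f$geometry
  den <- denoise_median(select_reference_slice(f$beta_stack)$image, 1)
  reg <- extract_fibre_regions(!binarize(den), ref_image = den)
  sarc <- locate_sarcolemma(reg, dim(den), 4)
  dil_wall <- EBImage::dilate(g$wall_mask * 1L, EBImage::makeBrush(3, "disc")) == 1
  expect_gte(mean(dil_wall[sarc$mask]), 0.8)
})

test_that("candidates on a straight horizontal band run along it", {
  band <- matrix(FALSE, 60, 60); band[30:33, ] <- TRUE
  sarc <- structure(dysquant:::sarcolemma_structure(band),
                    class = "sarcolemma_mask")
  cands <- propose_ellipses(sarc, semi_major_px = 3, semi_minor_px = 1.5,
                            spacing_px = 6)
  expect_gt(nrow(cands), 3)
  ang <- pmin(cands$theta, pi - cands$theta)   # distance from 0 mod pi
  expect_lt(max(ang), 0.2)

  single <- propose_ellipses(sarc, semi_major_px = 3, semi_minor_px = 1.5,
                             spacing_px = 1000)
  expect_equal(nrow(single), 1L)
})

test_that("a default field yields many high-overlap candidates", {
  f <- tiny_field("DMD", seed = 24)
  den <- denoise_median(select_reference_slice(f$beta_stack)$image, 1)
  bright <- binarize(den)
  reg <- extract_fibre_regions(!bright, ref_image = den)
  sarc <- locate_sarcolemma(reg, dim(den), 4)
  refined <- sarc$mask & bright
  sarc <- structure(dysquant:::sarcolemma_structure(refined),
                    class = "sarcolemma_mask")
  cands <- propose_ellipses(sarc)
  expect_gte(nrow(cands), 100)
  sc <- score_rois(cands, den, sarc)
  expect_gte(mean(sc$wall_overlap > 0.5), 0.95)
})

test_that("ROI scores match hand arithmetic", {
  band <- matrix(FALSE, 40, 40); band[19:22, ] <- TRUE
  sarc <- structure(dysquant:::sarcolemma_structure(band),
                    class = "sarcolemma_mask")
  img <- matrix(100, 40, 40); img[band] <- 1000

  aligned <- elliptical_roi(19.5, 20, 3, 1.5, 0)   # fully on-wall, aligned
  outside <- elliptical_roi(5, 20, 3, 1.5, 0)      # fully off-wall
  rotated <- elliptical_roi(19.5, 30, 1.5, 1.5, pi / 2)
  cands <- rbind(aligned, outside, rotated)
  sc <- score_rois(cands, img, sarc, weights = c(1, 1, 1) / 3)

  expect_equal(sc$brightness[1], 1)
  expect_equal(sc$orientation[1], 1, tolerance = 0.05)
  expect_equal(sc$wall_overlap[1], 1)
  expect_equal(sc$total[1], 1, tolerance = 0.02)
  expect_equal(sc$wall_overlap[2], 0)
  expect_equal(sc$brightness[2], 0.1)
  # hand check: total = (b + o + w) / 3 for each candidate
  expect_equal(sc$total,
               (sc$brightness + sc$orientation + sc$wall_overlap) / 3)

  far <- elliptical_roi(100, 100, 3, 1.5, 0)
  expect_error(score_rois(rbind(far), img, sarc), class = "dq_scoring_error")
  expect_error(score_rois(cands, img, sarc, weights = c(1, 1, 1)),
               class = "dq_parameter_error")
})

# independent oracle: full sort, then greedy overlap filtering by pixel sets
bf_select <- function(cands, scores, n, dims) {
  ord <- order(-scores$total, cands$center_row, cands$center_col)
  taken <- list(); sel <- integer(0)
  for (i in ord) {
    px <- dysquant::roi_pixels(cands[i, ], dims, check_bounds = FALSE)
    if (any(vapply(taken, function(t) any(t %in% px$idx), logical(1)))) next
    taken <- c(taken, list(px$idx)); sel <- c(sel, i)
    if (length(sel) == n) break
  }
  sel
}

test_that("select_top equals the brute-force greedy oracle", {
  for (seed in 1:4) {
    cands <- withr::with_seed(seed, data.frame(
      center_row = runif(50, 10, 90), center_col = runif(50, 10, 90),
      semi_major = 4, semi_minor = 2, theta = runif(50, 0, pi)))
    scores <- withr::with_seed(seed + 100, data.frame(
      brightness = runif(50), orientation = runif(50),
      wall_overlap = runif(50)))
    scores$total <- rowMeans(scores)
    out <- select_top(cands, scores, n = 26)
    oracle <- bf_select(cands, scores, 26, c(110, 110))
    expect_equal(out$rois$center_row, cands$center_row[oracle])
    expect_equal(out$scores$total, scores$total[oracle])
    expect_false(is.unsorted(rev(out$scores$total)))
  }
})

test_that("selection handles exhaustion, ties and overlaps", {
  # 40 non-overlapping candidates on a grid: exactly the 26 best totals
  grid <- expand.grid(r = seq(10, 80, 10), c = seq(10, 50, 10))
  cands <- data.frame(center_row = grid$r, center_col = grid$c,
                      semi_major = 3, semi_minor = 1.5, theta = 0)
  scores <- data.frame(brightness = 0, orientation = 0, wall_overlap = 0,
                       total = seq(0.99, 0.21, length.out = 40))
  out <- select_top(cands, scores, n = 26)
  expect_equal(nrow(out$rois), 26L)
  expect_false(out$shortfall)
  expect_equal(sort(out$scores$total, decreasing = TRUE),
               sort(scores$total, decreasing = TRUE)[1:26])

  few <- select_top(cands[1:10, ], scores[1:10, ], n = 26)
  expect_equal(nrow(few$rois), 10L)
  expect_true(few$shortfall)

  # identical scores, overlapping pair: the (row, col)-smaller wins
  two <- data.frame(center_row = c(20, 21), center_col = c(20, 20),
                    semi_major = 3, semi_minor = 2, theta = 0)
  sc2 <- data.frame(brightness = 1, orientation = 1, wall_overlap = 1, total = 1)
  sc2 <- rbind(sc2, sc2)
  picked <- select_top(two, sc2, n = 2)
  expect_equal(nrow(picked$rois), 1L)
  expect_equal(picked$rois$center_row, 20)
})

test_that("detect_rois finds 26 ROIs deterministically, blind to dystrophin", {
  f <- tiny_field("DMD", seed = 25)
  rs1 <- detect_rois(f$beta_stack, field_id = "f1")
  expect_s3_class(rs1, "roi_set")
  expect_equal(nrow(rs1$rois), 26L)
  expect_false(rs1$shortfall)

  rs2 <- detect_rois(f$beta_stack, field_id = "f1")
  expect_roi_sets_equal(rs1, rs2)

  # permuting the dystrophin cube cannot change the selection
  f$dys_stack$cube <- f$dys_stack$cube[, , rev(seq_len(dim(f$dys_stack$cube)[3]))]
  rs3 <- detect_rois(f$beta_stack, field_id = "f1")
  expect_roi_sets_equal(rs1, rs3)
})

test_that("selected ROIs sit on the true wall across seeds", {
  ov <- unlist(lapply(1:3, function(seed) {
    f <- tiny_field("DMD", seed = 30 + seed)
    g <- f$geometry
    rs <- detect_rois(f$beta_stack)
    vapply(seq_len(nrow(rs$rois)), function(i) {
      px <- dysquant::roi_pixels(rs$rois[i, ], c(g$rows, g$cols))
      mean(g$wall_mask[px$idx])
    }, numeric(1))
  }))
  expect_gte(mean(ov), 0.85)
})
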