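# Sarcolemma band geometry: ridge, thickness and tangent orientation derived
# from a binary wall-band mask.
sarcolemma_structure <- function(mask) {
  storage.mode(mask) <- "integer"
  # pad with background so the frame edge bounds the band like any other edge
  padded <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  dist <- EBImage::distmap(padded)
  dist <- matrix(as.numeric(dist), nrow(padded), ncol(padded))
  dist <- dist[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  # ridge: local maxima of the distance transform inside the band
  dmax <- EBImage::dilate(dist, EBImage::makeBrush(3, "box"))
  ridge <- mask == 1L & dist >= as.numeric(dmax) - 1e-6
  thickness <- if (any(ridge)) 2 * stats::median(dist[ridge]) else 0

  # structure tensor of the smoothed band: dominant eigenvector = band
  # normal; tangent is its perpendicular
  g <- EBImage::gblur(mask * 1.0, sigma = 2)
  g <- matrix(as.numeric(g), nrow(mask), ncol(mask))
  gx <- g * 0; gy <- g * 0
  gx[, 2:(ncol(g) - 1)] <- (g[, 3:ncol(g)] - g[, 1:(ncol(g) - 2)]) / 2
  gy[2:(nrow(g) - 1), ] <- (g[3:nrow(g), ] - g[1:(nrow(g) - 2), ]) / 2
  sm <- function(x) matrix(as.numeric(EBImage::gblur(x, sigma = 2)), nrow(x), ncol(x))
  jxx <- sm(gx * gx); jyy <- sm(gy * gy); jxy <- sm(gx * gy)
  normal <- 0.5 * atan2(2 * jxy, jxx - jyy)
  tangent <- (normal + pi / 2) %% pi

  list(mask = mask == 1L, thickness_px = thickness, tangent_field = tangent,
       dist = dist, ridge = ridge)
}

#' Locate the sarcolemma between detected fibres
#'
#' Dilates the fibre regions and takes the dilated area outside the original
#' regions: the inter-fibre band where the sarcolemma lies. The band's
#' typical thickness is estimated from its distance transform and a local
#' tangent orientation field from its structure tensor.
#'
#' @param regions A [extract_fibre_regions()] result with >= 1 region.
#' @param image_shape `c(rows, cols)`.
#' @param dilation_radius_px Disc radius of the dilation.
#' @return Object of class `sarcolemma_mask`: `mask`, `thickness_px`,
#'   `tangent_field` (radians in `[0, pi)`), plus the distance transform and
#'   ridge used downstream.
#' @export
locate_sarcolemma <- function(regions, image_shape, dilation_radius_px = 4L) {
  if (!inherits(regions, "fibre_regions") || nrow(regions$regions) < 1L)
    stop_dq("locate_sarcolemma needs at least one fibre region",
            class = "dq_empty_input_error")
  interior <- regions$labels > 0L
  storage.mode(interior) <- "integer"
  brush <- EBImage::makeBrush(2L * dilation_radius_px + 1L, shape = "disc")
  dil <- EBImage::dilate(interior, brush)
  band <- (as.matrix(dil) == 1L) & !(interior == 1L)
  structure(sarcolemma_structure(band), class = "sarcolemma_mask")
}

#' Propose candidate membrane ellipses
#'
#' Candidate ROIs are centered on the band's ridge (skeleton) pixels thinned
#' greedily in (row, col) scan order so accepted centers stay at least
#' `spacing_px` apart; each candidate's major axis follows the local wall
#' tangent. Candidates whose rasterization would leave the image are
#' dropped.
#'
#' @param sarc A [locate_sarcolemma()] result (non-empty mask).
#' @param semi_major_px,semi_minor_px Ellipse semi-axes; defaults derive
#'   from the measured band thickness (`semi_minor = max(1, t/2 - 0.5)`,
#'   `semi_major = 2 * semi_minor`).
#' @param spacing_px Minimum center spacing (default `2 * semi_major_px`).
#' @return ROI data frame of candidates.
#' @export
propose_ellipses <- function(sarc, semi_major_px = NULL, semi_minor_px = NULL,
                             spacing_px = NULL) {
  if (!any(sarc$mask))
    stop_dq("empty sarcolemma mask", class = "dq_empty_input_error")
  semi_minor_px <- semi_minor_px %||% max(1, sarc$thickness_px / 2 - 0.5)
  semi_major_px <- semi_major_px %||% (2 * semi_minor_px)
  if (semi_major_px < semi_minor_px)
    stop_dq("semi_major_px must be >= semi_minor_px", class = "dq_parameter_error")
  spacing_px <- spacing_px %||% (2 * semi_major_px)
  R <- nrow(sarc$mask); C <- ncol(sarc$mask)
  idx <- which(sarc$ridge)
  rows0 <- (idx - 1L) %% R
  cols0 <- (idx - 1L) %/% R
  theta <- sarc$tangent_field[idx] %% pi
  # clip to image bounds first (analytic ellipse extents), then thin
  ct <- cos(theta); st <- sin(theta)
  ext_row <- sqrt((semi_major_px * st)^2 + (semi_minor_px * ct)^2)
  ext_col <- sqrt((semi_major_px * ct)^2 + (semi_minor_px * st)^2)
  ok <- rows0 - ext_row >= 0 & rows0 + ext_row <= R - 1 &
    cols0 - ext_col >= 0 & cols0 + ext_col <= C - 1
  rows0 <- rows0[ok]; cols0 <- cols0[ok]; theta <- theta[ok]
  ord <- order(rows0, cols0)
  rows0 <- rows0[ord]; cols0 <- cols0[ord]; theta <- theta[ord]
  acc_r <- numeric(0); acc_c <- numeric(0); keep <- integer(0)
  sp2 <- spacing_px^2
  for (j in seq_along(rows0)) {
    if (length(acc_r) == 0 ||
        min((acc_r - rows0[j])^2 + (acc_c - cols0[j])^2) >= sp2) {
      acc_r <- c(acc_r, rows0[j]); acc_c <- c(acc_c, cols0[j])
      keep <- c(keep, j)
    }
  }
  data.frame(center_row = rows0[keep], center_col = cols0[keep],
             semi_major = semi_major_px, semi_minor = semi_minor_px,
             theta = theta[keep])
}

#' Score candidate ROIs
#'
#' Each candidate gets three components in `[0, 1]`: `brightness` (mean
#' reference-slice intensity inside the ROI, normalized by the field
#' maximum), `orientation` (`|cos|` of the angle between the ROI's major
#' axis and the local wall tangent) and `wall_overlap` (fraction of ROI
#' pixels on the wall minus fraction off it, clipped to `[0, 1]`). The total
#' is their convex combination with the given weights.
#'
#' @param cands ROI data frame.
#' @param ref_image Reference wavelength slice.
#' @param sarc A `sarcolemma_mask`.
#' @param weights Length-3 non-negative weights `(brightness, orientation,
#'   wall_overlap)` summing to 1.
#' @return Data frame with `brightness`, `orientation`, `wall_overlap`,
#'   `total` (one row per candidate).
#' @export
score_rois <- function(cands, ref_image, sarc, weights = c(1, 1, 1) / 3) {
  if (length(weights) != 3 || any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop_dq("weights must be 3 non-negative values summing to 1",
            class = "dq_parameter_error")
  fmax <- max(ref_image)
  if (fmax <= 0) fmax <- 1
  dims <- dim(ref_image)
  n <- nrow(cands)
  out <- data.frame(brightness = numeric(n), orientation = numeric(n),
                    wall_overlap = numeric(n), total = numeric(n))
  for (i in seq_len(n)) {
    px <- tryCatch(roi_pixels(cands[i, ], dims), error = function(e)
      stop_dq("cannot score ROI ", i, " at (", cands$center_row[i], ",",
              cands$center_col[i], "): ", conditionMessage(e),
              class = "dq_scoring_error"))
    b <- mean(ref_image[px$idx]) / fmax
    ci <- round(cands$center_row[i]) + 1
    cj <- round(cands$center_col[i]) + 1
    tangent <- sarc$tangent_field[ci, cj]
    o <- abs(cos(cands$theta[i] - tangent))
    f <- mean(sarc$mask[px$idx])
    w <- min(1, max(0, f - (1 - f)))
    out$brightness[i] <- b
    out$orientation[i] <- o
    out$wall_overlap[i] <- w
    out$total[i] <- sum(weights * c(b, o, w))
  }
  out
}

#' Select the best-ranked non-overlapping ROIs
#'
#' Greedy selection in descending total-score order (ties broken by (row,
#' col) of the center), skipping any candidate whose rasterized pixel set
#' intersects an already selected ROI; stops at `n` or exhaustion.
#'
#' @param cands ROI data frame.
#' @param scores Matching data frame from [score_rois()].
#' @param n Number of ROIs to select (default 26).
#' @param field_id Free-text identifier stored on the result.
#' @return Object of class `roi_set`: `field_id`, `rois`, `scores` (sorted
#'   non-increasing by total), `n_requested`, `shortfall`.
#' @export
select_top <- function(cands, scores, n = 26L, field_id = "") {
  if (nrow(cands) != nrow(scores))
    stop_dq("cands and scores are not aligned", class = "dq_parameter_error")
  ext_r <- max(0, cands$center_row + cands$semi_major)
  ext_c <- max(0, cands$center_col + cands$semi_major)
  dims <- c(ceiling(ext_r) + 2L, ceiling(ext_c) + 2L)
  ord <- order(-scores$total, cands$center_row, cands$center_col)
  occupied <- logical(prod(dims))
  sel <- integer(0)
  for (i in ord) {
    px <- roi_pixels(cands[i, ], dims, check_bounds = FALSE)
    if (any(occupied[px$idx])) next
    occupied[px$idx] <- TRUE
    sel <- c(sel, i)
    if (length(sel) == n) break
  }
  rois <- cands[sel, , drop = FALSE]
  sc <- scores[sel, , drop = FALSE]
  rownames(rois) <- NULL; rownames(sc) <- NULL
  structure(list(field_id = field_id, rois = rois, scores = sc,
                 n_requested = as.integer(n),
                 shortfall = length(sel) < n),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> field '%s': %d/%d ROIs%s\n", x$field_id,
              nrow(x$rois), x$n_requested,
              if (x$shortfall) " (shortfall)" else ""))
  invisible(x)
}

#' Automatic sarcolemma ROI detection
#'
#' Full detection pipeline on the beta-spectrin (membrane guide) channel:
#' reference-slice selection, median denoising, Otsu binarization,
#' morphological fibre extraction, sarcolemma location by dilation, ellipse
#' proposal on the wall ridge, scoring by brightness / orientation / wall
#' overlap, and greedy selection of the best `n_rois` non-overlapping
#' ellipses. Deterministic: identical stack and configuration give an
#' identical ROI set. Only the membrane channel is used, so the selection is
#' blind to the dystrophin signal.
#'
#' @param beta_stack The beta-spectrin [spectral_stack()].
#' @param config A [pipeline_config()].
#' @param field_id Identifier stored on the result.
#' @return A `roi_set` with extra fields `ref_slice_index` and `threshold`.
#' @export
detect_rois <- function(beta_stack, config = pipeline_config(), field_id = "") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "dq_stage_error")) stop(e)
      stop_dq("[", name, "] ", conditionMessage(e), class = "dq_stage_error")
    })
  }
  ref <- stage("reference_slice", select_reference_slice(beta_stack))
  den <- stage("median_filter",
               denoise_median(ref$image, config$median_radius_px))
  bright <- stage("binarize",
                  binarize(den, config$binarize_method, config$binarize_threshold))
  regions <- stage("fibre_regions",
                   extract_fibre_regions(!bright, config$min_area_px,
                                         config$min_circularity,
                                         config$morphology_radius_px,
                                         ref_image = den))
  sarc <- stage("sarcolemma",
                locate_sarcolemma(regions, dim(den), config$dilation_radius_px))
  if (isTRUE(config$refine_band)) {
    refined <- sarc$mask & bright
    if (any(refined))
      sarc <- structure(sarcolemma_structure(refined), class = "sarcolemma_mask")
  }
  cands <- stage("propose",
                 propose_ellipses(sarc, config$semi_major_px,
                                  config$semi_minor_px, config$spacing_px))
  scores <- stage("score", score_rois(cands, den, sarc, config$weights))
  out <- stage("select", select_top(cands, scores, config$n_rois, field_id))
  out$ref_slice_index <- ref$slice_index
  out$threshold <- attr(bright, "threshold")
  out
}
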