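#' Select the reference wavelength slice
#'
#' The fibre-detection pipeline works on the single wavelength window with
#' the highest fluorescence: the slice whose mean intensity is maximal (ties
#' broken towards the lowest index).
#'
#' @param stack A [spectral_stack()].
#' @return List with `slice_index` (1-based) and `image` (that slice).
#' @export
select_reference_slice <- function(stack) {
  if (!inherits(stack, "spectral_stack"))
    stop_dq("stack must be a spectral_stack", class = "dq_stack_error")
  means <- apply(stack$cube, 3, mean)
  k <- which.max(means)                       # which.max ties -> lowest index
  list(slice_index = k, image = stack$cube[, , k])
}

# reflect-101 padding indices (mirror about the edge pixel, no duplication)
reflect_idx <- function(n, r) {
  if (r >= n)
    stop_dq("median radius too large for the image", class = "dq_parameter_error")
  i <- (1 - r):(n + r)
  i <- abs(i - 1) %% (2 * (n - 1))
  ifelse(i >= n, 2 * (n - 1) - i, i) + 1L
}

#' Median denoising filter
#'
#' Each output pixel is the exact median of its `(2r+1) x (2r+1)`
#' neighbourhood; edges are handled by mirror reflection. Implemented as a
#' fully vectorized sorting network over the shifted neighbourhood planes, so
#' results are exact (no histogram approximation).
#'
#' @param image 2-D numeric matrix.
#' @param radius_px Neighbourhood radius in pixels (>= 1).
#' @return Matrix of the same shape.
#' @export
denoise_median <- function(image, radius_px = 1L) {
  if (!is_count(radius_px, 1))
    stop_dq("radius_px must be a positive integer", class = "dq_parameter_error")
  r <- as.integer(radius_px)
  R <- nrow(image); C <- ncol(image)
  pad <- image[reflect_idx(R, r), reflect_idx(C, r)]
  k <- (2L * r + 1L)^2
  m <- matrix(0, R * C, k)
  t <- 1L
  for (dc in 0:(2L * r)) for (dr in 0:(2L * r)) {
    m[, t] <- pad[dr + seq_len(R), dc + seq_len(C)]
    t <- t + 1L
  }
  # odd-even transposition sort across neighbourhood columns
  for (pass in seq_len(k)) {
    j <- if (pass %% 2L) 1L else 2L
    while (j + 1L <= k) {
      a <- m[, j]; b <- m[, j + 1L]
      m[, j] <- pmin(a, b); m[, j + 1L] <- pmax(a, b)
      j <- j + 2L
    }
  }
  matrix(m[, (k + 1L) %/% 2L], R, C)
}

#' Binarize an intensity image
#'
#' With `method = "otsu"` the threshold maximizes the between-class variance
#' over the integer intensity histogram (exhaustive sweep; ties broken
#' towards the lowest threshold). The mask is `image > threshold`.
#'
#' @param image 2-D matrix of non-negative integer-valued intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required for `method = "fixed"`.
#' @return Logical mask with attribute `threshold`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold))
      stop_dq("fixed binarization requires a threshold", class = "dq_parameter_error")
    thr <- threshold
  } else {
    v <- as.integer(round(image))
    if (diff(range(v)) == 0L)
      stop_dq("cannot Otsu-threshold a constant image",
              class = "dq_degenerate_error")
    thr <- otsu_threshold(v)
  }
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

# Exhaustive between-class-variance sweep over integer levels.
otsu_threshold <- function(v) {
  lev <- min(v):max(v)
  h <- tabulate(v - min(v) + 1L, length(lev))
  tot <- sum(h)
  w0 <- cumsum(h)
  mu <- cumsum(h * lev)
  mt <- mu[length(mu)]
  m0 <- mu / w0
  m1 <- (mt - mu) / (tot - w0)
  bc <- (w0 / tot) * (1 - w0 / tot) * (m0 - m1)^2
  bc[!is.finite(bc)] <- -1
  lev[which.max(bc)]
}

#' Extract fibre regions from a binary mask
#'
#' Takes a fibre-interior-bright mask (i.e. the complement of the bright
#' membrane mask), cleans it morphologically (binary opening with a disc,
#' hole filling, removal of frame-touching components) and keeps connected
#' components that are large and roughly circular enough to be muscle-fibre
#' cross sections. Regions are labelled 1..K in decreasing area order.
#'
#' @param mask Logical matrix, interior-bright.
#' @param min_area_px Minimum component area (pixels).
#' @param min_circularity Minimum `4*pi*area / perimeter^2`.
#' @param morphology_radius_px Disc radius of the opening.
#' @param ref_image Optional intensity image used to record each region's
#'   mean intensity.
#' @return Object of class `fibre_regions`: `labels` (integer matrix) and
#'   `regions` (data frame with `label`, `area_px`, `centroid_row`,
#'   `centroid_col` (0-based), `circularity`, `mean_intensity`).
#' @export
extract_fibre_regions <- function(mask, min_area_px = 300L,
                                  min_circularity = 0.3,
                                  morphology_radius_px = 2L,
                                  ref_image = NULL) {
  storage.mode(mask) <- "integer"
  brush <- EBImage::makeBrush(2L * morphology_radius_px + 1L, shape = "disc")
  m <- EBImage::opening(mask, brush)
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  R <- nrow(lab); C <- ncol(lab)
  border_labels <- setdiff(unique(c(lab[c(1, R), ], lab[, c(1, C)])), 0)
  if (length(border_labels)) lab[lab %in% border_labels] <- 0L

  empty <- list(labels = matrix(0L, R, C),
                regions = data.frame(label = integer(0), area_px = integer(0),
                                     centroid_row = numeric(0),
                                     centroid_col = numeric(0),
                                     circularity = numeric(0),
                                     mean_intensity = numeric(0)))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids)) return(structure(empty, class = "fibre_regions"))

  shp <- EBImage::computeFeatures.shape(lab)
  present <- as.integer(rownames(shp))
  area <- shp[, "s.area"]
  per <- shp[, "s.perimeter"]
  circ <- 4 * pi * area / per^2
  keep <- present[area >= min_area_px & circ >= min_circularity]
  if (!length(keep)) return(structure(empty, class = "fibre_regions"))

  keep <- keep[order(-area[match(keep, present)])]
  out_lab <- matrix(0L, R, C)
  rows <- row(lab); cols <- col(lab)
  regions <- data.frame(label = seq_along(keep), area_px = NA_integer_,
                        centroid_row = NA_real_, centroid_col = NA_real_,
                        circularity = NA_real_, mean_intensity = NA_real_)
  for (j in seq_along(keep)) {
    sel <- lab == keep[j]
    out_lab[sel] <- j
    regions$area_px[j] <- sum(sel)
    regions$centroid_row[j] <- mean(rows[sel]) - 1
    regions$centroid_col[j] <- mean(cols[sel]) - 1
    regions$circularity[j] <- circ[match(keep[j], present)]
    if (!is.null(ref_image)) regions$mean_intensity[j] <- mean(ref_image[sel])
  }
  structure(list(labels = out_lab, regions = regions), class = "fibre_regions")
}

#' @export
print.fibre_regions <- function(x, ...) {
  cat(sprintf("<fibre_regions> %d regions, median area %.0f px\n",
              nrow(x$regions), stats::median(x$regions$area_px)))
  invisible(x)
}
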