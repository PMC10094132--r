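#' Elliptical regions of interest on the sarcolemma
#'
#' ROIs are small ellipses placed on the muscle-fibre membrane. Coordinates
#' follow the raster convention: 0-based `(row, col)` with the origin at the
#' top-left corner and rows increasing downward; `theta` is the orientation of
#' the major axis in radians measured from the +col axis, reduced to
#' `[0, pi)`. A set of ROIs is represented as a data frame with columns
#' `center_row`, `center_col`, `semi_major`, `semi_minor`, `theta` (extra
#' columns such as `field_id` are carried along untouched).
#'
#' @param center_row,center_col Ellipse center in 0-based pixel coordinates.
#' @param semi_major,semi_minor Semi-axes in pixels; `semi_major >=
#'   semi_minor > 0`.
#' @param theta Major-axis orientation in radians.
#' @return A one-row ROI data frame.
#' @export
elliptical_roi <- function(center_row, center_col, semi_major, semi_minor,
                           theta = 0) {
  df <- data.frame(center_row = as.numeric(center_row),
                   center_col = as.numeric(center_col),
                   semi_major = as.numeric(semi_major),
                   semi_minor = as.numeric(semi_minor),
                   theta = as.numeric(theta) %% pi)
  validate_rois(df)
}

roi_columns <- c("center_row", "center_col", "semi_major", "semi_minor", "theta")

#' Validate an ROI data frame
#'
#' Checks the ellipse invariants (`semi_major >= semi_minor > 0`, finite
#' fields, `theta` reducible to `[0, pi)`) and returns the data frame with
#' `theta` normalized.
#'
#' @param rois ROI data frame (see [elliptical_roi()]).
#' @return The validated data frame.
#' @export
validate_rois <- function(rois) {
  if (!is.data.frame(rois) || !all(roi_columns %in% names(rois)))
    stop_dq("ROI table must have columns ", paste(roi_columns, collapse = ", "),
            class = "dq_roi_error")
  num <- vapply(rois[roi_columns], is.numeric, logical(1))
  if (!all(num) || anyNA(rois[roi_columns]) ||
      !all(vapply(rois[roi_columns], function(x) all(is.finite(x)), logical(1))))
    stop_dq("ROI fields must be finite numerics", class = "dq_roi_error")
  if (any(rois$semi_minor <= 0) || any(rois$semi_major < rois$semi_minor))
    stop_dq("ROIs require semi_major >= semi_minor > 0", class = "dq_roi_error")
  rois$theta <- rois$theta %% pi
  rois
}

# Half-extent of the rotated ellipse along the row and col directions.
roi_extent <- function(roi) {
  ct <- cos(roi$theta); st <- sin(roi$theta)
  list(row = sqrt((roi$semi_major * st)^2 + (roi$semi_minor * ct)^2),
       col = sqrt((roi$semi_major * ct)^2 + (roi$semi_minor * st)^2))
}

#' Rasterize an elliptical ROI
#'
#' A pixel belongs to the ellipse iff its center satisfies the ellipse
#' inequality (orientation-aware, `<= 1`). Returns the member pixels as
#' 1-based matrix indices into a rows x cols image.
#'
#' @param roi One-row ROI data frame.
#' @param image_dim `c(rows, cols)` of the target image.
#' @param check_bounds Error if any member pixel falls outside the image
#'   (default TRUE); with FALSE, out-of-bounds pixels are an error only when
#'   the whole raster is empty.
#' @return List with integer vectors `rows`, `cols` (1-based) and `idx`
#'   (linear index into the image matrix).
#' @export
roi_pixels <- function(roi, image_dim, check_bounds = TRUE) {
  R <- image_dim[1]; C <- image_dim[2]
  ext <- roi_extent(roi)
  r0 <- floor(roi$center_row - ext$row); r1 <- ceiling(roi$center_row + ext$row)
  c0 <- floor(roi$center_col - ext$col); c1 <- ceiling(roi$center_col + ext$col)
  if (check_bounds && (r0 < 0 || c0 < 0 || r1 > R - 1 || c1 > C - 1)) {
    # bounding box may exceed the ellipse; verify on the actual raster below
    ok_box <- FALSE
  } else ok_box <- TRUE
  rr <- seq(max(r0, 0), min(r1, R - 1))
  cc <- seq(max(c0, 0), min(c1, C - 1))
  if (length(rr) == 0L || length(cc) == 0L)
    stop_dq("ROI rasterizes to no pixels inside the image", class = "dq_roi_error")
  dy <- rep(rr, times = length(cc)) - roi$center_row
  dx <- rep(cc, each = length(rr)) - roi$center_col
  ct <- cos(roi$theta); st <- sin(roi$theta)
  u <- (dx * ct + dy * st) / roi$semi_major
  v <- (-dx * st + dy * ct) / roi$semi_minor
  inside <- u * u + v * v <= 1
  rows <- rep(rr, times = length(cc))[inside] + 1L
  cols <- rep(cc, each = length(rr))[inside] + 1L
  if (length(rows) == 0L)
    stop_dq("ROI rasterizes to no pixels inside the image", class = "dq_roi_error")
  if (check_bounds && !ok_box) {
    # the clipped raster lost pixels iff the unclipped ellipse leaves the frame
    full_rr <- r0:r1; full_cc <- c0:c1
    dyf <- rep(full_rr, times = length(full_cc)) - roi$center_row
    dxf <- rep(full_cc, each = length(full_rr)) - roi$center_col
    uf <- (dxf * ct + dyf * st) / roi$semi_major
    vf <- (-dxf * st + dyf * ct) / roi$semi_minor
    if (sum(uf * uf + vf * vf <= 1) != length(rows))
      stop_dq("ROI extends outside the image bounds", class = "dq_roi_error")
  }
  list(rows = rows, cols = cols, idx = rows + (cols - 1L) * R)
}

# TRUE when the rasterized pixel sets of two ROIs intersect.
rois_overlap <- function(px_a, px_b) any(px_a$idx %in% px_b$idx)

#' Read and write ROI sets as CSV
#'
#' The on-disk dialect is a plain CSV with the ROI columns `center_row`,
#' `center_col`, `semi_major`, `semi_minor`, `theta` (0-based pixel
#' coordinates, radians; see [elliptical_roi()]); any additional columns (for
#' example `field_id`) round-trip unchanged. Float fields are written with
#' enough digits to round-trip within 1e-6.
#'
#' @param path CSV file path.
#' @return `read_roi_set()`: a validated ROI data frame in file order.
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path))
    stop_dq("ROI file not found: ", path, class = "dq_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(roi_columns %in% names(df)))
    stop_dq("ROI file lacks required columns (unsupported record type?): ",
            path, class = "dq_roi_error")
  if (nrow(df) == 0L) {
    df[roi_columns] <- lapply(df[roi_columns], as.numeric)
    return(df)
  }
  validate_rois(df)
}

#' @rdname read_roi_set
#' @param rois ROI data frame to write (may be empty: a header-only file).
#' @return `write_roi_set()`: `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  if (nrow(rois) > 0) rois <- validate_rois(rois)
  else if (!all(roi_columns %in% names(rois)))
    rois <- stats::setNames(as.data.frame(rep(list(numeric(0)), length(roi_columns))),
                            roi_columns)
  num <- vapply(rois, is.numeric, logical(1))
  rois[num] <- lapply(rois[num], function(x) signif(x, 12))
  ok <- tryCatch({ utils::write.csv(rois, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_dq("cannot write ROI file: ", path, class = "dq_io_error")
  invisible(path)
}
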