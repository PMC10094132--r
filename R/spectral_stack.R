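#' Construct a spectral (x-y-lambda) image stack
#'
#' A `spectral_stack` holds one channel's intensity cube of dimensions
#' rows x cols x n_lambda together with its wavelength axis and acquisition
#' metadata. Intensities are integer-valued arbitrary units bounded by the
#' encoding depth (12 bits by default, so 0..4095).
#'
#' @param cube Numeric array, rows x cols x n_lambda; values must be integers
#'   in `[0, 2^bit_depth - 1]`.
#' @param axis A [wavelength_axis()] with one center per cube slice.
#' @param excitation_nm Excitation wavelength (nm).
#' @param pixel_size_um Linear pixel pitch (micrometres per pixel).
#' @param bit_depth Encoding depth in bits (default 12).
#' @param channel_label Free-text channel name (e.g. the antibody).
#' @return An object of class `spectral_stack`.
#' @export
spectral_stack <- function(cube, axis, excitation_nm, pixel_size_um = 0.361,
                           bit_depth = 12L, channel_label = "") {
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop_dq("cube must be a 3-D array (rows x cols x n_lambda)",
            class = "dq_stack_error")
  if (!inherits(axis, "wavelength_axis"))
    stop_dq("axis must be a wavelength_axis", class = "dq_stack_error")
  if (dim(cube)[3] != length(axis$centers_nm))
    stop_dq("cube has ", dim(cube)[3], " slices but the axis has ",
            length(axis$centers_nm), " centers", class = "dq_stack_error")
  if (dim(cube)[1] < 1 || dim(cube)[2] < 1)
    stop_dq("cube must have at least one row and column", class = "dq_stack_error")
  if (!is_count(bit_depth, 1))
    stop_dq("bit_depth must be a positive integer", class = "dq_stack_error")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_dq("pixel_size_um must be positive", class = "dq_stack_error")
  storage.mode(cube) <- "double"
  ceiling_au <- 2^bit_depth - 1
  rng <- range(cube)
  if (anyNA(rng) || rng[1] < 0 || rng[2] > ceiling_au)
    stop_dq("cube intensities must lie in [0, ", ceiling_au, "]",
            class = "dq_stack_error")
  structure(list(cube = cube, axis = axis,
                 excitation_nm = as.numeric(excitation_nm),
                 pixel_size_um = as.numeric(pixel_size_um),
                 bit_depth = as.integer(bit_depth),
                 channel_label = as.character(channel_label)),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<spectral_stack> '%s' %dx%d px, %d lambda slices (%.2f-%.2f nm), ex %.0f nm, %d-bit, %.3f um/px\n",
              x$channel_label, d[1], d[2], d[3],
              x$axis$centers_nm[1], x$axis$centers_nm[d[3]],
              x$excitation_nm, x$bit_depth, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.spectral_stack <- function(x) dim(x$cube)
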