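#' Emission wavelength axis of a spectral stack
#'
#' A lambda stack is acquired by sliding a detection window of fixed
#' `bandwidth_nm` across the emission spectrum in steps of `step_nm`;
#' consecutive windows may overlap (bandwidth larger than step is legal and is
#' the default acquisition geometry here: 15 nm windows every 5.21 nm).
#' `wavelength_axis()` builds the axis from an acquisition range: centers run
#' from `start_nm` upwards in steps of `step_nm`, keeping every center not
#' exceeding `stop_nm`.
#'
#' @param start_nm First window center (nm).
#' @param stop_nm Upper bound for window centers (nm); the last center is the
#'   largest `start_nm + k * step_nm` that is `<= stop_nm`.
#' @param step_nm Center-to-center spacing (nm), positive.
#' @param bandwidth_nm Detection window width (nm), positive.
#' @return An object of class `wavelength_axis`: a list with `centers_nm`,
#'   `step_nm` and `bandwidth_nm`.
#' @examples
#' ax <- wavelength_axis(485, 625, 5.21, 15)   # dystrophin/AF488-type channel
#' length(ax$centers_nm)                        # 27 windows
#' @export
wavelength_axis <- function(start_nm, stop_nm, step_nm, bandwidth_nm) {
  if (!is.numeric(step_nm) || step_nm <= 0)
    stop_dq("step_nm must be positive", class = "dq_axis_error")
  if (!is.numeric(bandwidth_nm) || bandwidth_nm <= 0)
    stop_dq("bandwidth_nm must be positive", class = "dq_axis_error")
  if (start_nm >= stop_nm)
    stop_dq("start_nm must be below stop_nm", class = "dq_axis_error")
  n <- floor((stop_nm - start_nm) / step_nm + 1e-9) + 1L
  centers <- start_nm + step_nm * (seq_len(n) - 1L)
  new_wavelength_axis(centers, step_nm, bandwidth_nm)
}

# Low-level constructor from explicit centers (used by the sidecar reader).
new_wavelength_axis <- function(centers_nm, step_nm, bandwidth_nm) {
  centers_nm <- as.numeric(centers_nm)
  if (length(centers_nm) < 1L || anyNA(centers_nm))
    stop_dq("axis needs at least one finite center", class = "dq_axis_error")
  if (length(centers_nm) > 1L) {
    d <- diff(centers_nm)
    if (any(d <= 0))
      stop_dq("axis centers must be strictly increasing", class = "dq_axis_error")
    if (any(abs(d - step_nm) > 1e-6))
      stop_dq("axis center spacing does not match step_nm", class = "dq_axis_error")
  }
  if (step_nm <= 0 || bandwidth_nm <= 0)
    stop_dq("step_nm and bandwidth_nm must be positive", class = "dq_axis_error")
  structure(list(centers_nm = centers_nm, step_nm = as.numeric(step_nm),
                 bandwidth_nm = as.numeric(bandwidth_nm)),
            class = "wavelength_axis")
}

#' @export
print.wavelength_axis <- function(x, ...) {
  n <- length(x$centers_nm)
  cat(sprintf("<wavelength_axis> %d windows, %.2f-%.2f nm, step %.2f nm, bandwidth %.1f nm\n",
              n, x$centers_nm[1], x$centers_nm[n], x$step_nm, x$bandwidth_nm))
  invisible(x)
}

#' @export
length.wavelength_axis <- function(x) length(x$centers_nm)

axes_equal <- function(a, b, tol = 1e-6) {
  length(a$centers_nm) == length(b$centers_nm) &&
    all(abs(a$centers_nm - b$centers_nm) < tol) &&
    abs(a$step_nm - b$step_nm) < tol &&
    abs(a$bandwidth_nm - b$bandwidth_nm) < tol
}

# Default acquisition axes for the two channels.
#' Default detection axes for the dystrophin and beta-spectrin channels
#'
#' The dystrophin (AF488-type) channel is collected from 485 to 625 nm and the
#' beta-spectrin (Cy5-type) channel from 590 to 780 nm, both with 15 nm
#' detection windows stepped by 5.21 nm.
#' @return A `wavelength_axis`.
#' @export
dys_axis <- function() wavelength_axis(485, 625, 5.21, 15)

#' @rdname dys_axis
#' @export
beta_axis <- function() wavelength_axis(590, 780, 5.21, 15)
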