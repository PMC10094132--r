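#' Fluorophore emission model
#'
#' Emission spectra are modelled as Gaussians in wavelength; the signal
#' recorded in a detection window is the integral of the Gaussian over the
#' window. Responses are normalized so that the brightest window of the
#' channel's own axis carries exactly the nominal class intensity, which
#' makes the rendered peak-window wall intensity equal to `wall_mean` and
#' keeps the ground truth analytic.
#'
#' @param peak_nm Emission-peak wavelength (nm).
#' @param sigma_nm Gaussian spectral width (nm), positive.
#' @param amplitude Relative emission amplitude (> 0).
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(peak_nm, sigma_nm, amplitude = 1) {
  if (!is.numeric(sigma_nm) || sigma_nm <= 0)
    stop_dq("sigma_nm must be positive", class = "dq_parameter_error")
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop_dq("amplitude must be positive", class = "dq_parameter_error")
  structure(list(peak_nm = peak_nm, sigma_nm = sigma_nm, amplitude = amplitude),
            class = "fluorophore_model")
}

# Unnormalized window integrals of the Gaussian emission line over each
# detection window of `axis`.
window_integrals <- function(fluor, axis) {
  lo <- axis$centers_nm - axis$bandwidth_nm / 2
  hi <- axis$centers_nm + axis$bandwidth_nm / 2
  pnorm(hi, fluor$peak_nm, fluor$sigma_nm) - pnorm(lo, fluor$peak_nm, fluor$sigma_nm)
}

# Relative per-window response, normalized to 1 at the brightest window of
# the fluorophore's native axis (pass `native_axis` for bleed-through terms).
window_response <- function(fluor, axis, native_axis = axis) {
  ints <- window_integrals(fluor, axis)
  ref <- max(window_integrals(fluor, native_axis))
  fluor$amplitude * ints / ref
}

#' Per-group intensity parameters for the simulator
#'
#' @param group_label One of `"DMD"`, `"BMD"`, `"CONTROL"`.
#' @param wall_mean Mean sarcolemma intensity at the emission-peak window
#'   (a.u. on the 12-bit scale).
#' @param wall_sd Between-ROI (wall-segment) standard deviation (a.u.).
#' @param cytoplasm_frac,background_frac Interior / background intensity as
#'   fractions of `wall_mean`, in `[0, 1)`.
#' @param vessel_frac,adipose_frac,connective_frac Confounder-class intensity
#'   as fractions of `wall_mean`.
#' @param readout_sd Gaussian readout noise SD (a.u.).
#' @param shot_scale Shot-noise scale: the noise variance at a voxel is
#'   `readout_sd^2 + shot_scale * signal` (Gaussian approximation of Poisson
#'   photon noise).
#' @return An object of class `group_intensity_params`.
#' @export
group_intensity_params <- function(group_label = c("DMD", "BMD", "CONTROL"),
                                   wall_mean, wall_sd = 0.1 * wall_mean,
                                   cytoplasm_frac = 0.10,
                                   background_frac = 0.02,
                                   vessel_frac = 0.5, adipose_frac = 0.08,
                                   connective_frac = 0.15,
                                   readout_sd = 10, shot_scale = 2) {
  group_label <- match.arg(group_label)
  if (!is.numeric(wall_mean) || wall_mean < 0)
    stop_dq("wall_mean must be >= 0", class = "dq_parameter_error")
  fr <- c(cytoplasm_frac, background_frac)
  if (any(fr < 0) || any(fr >= 1))
    stop_dq("cytoplasm_frac and background_frac must lie in [0, 1)",
            class = "dq_parameter_error")
  if (wall_sd < 0 || readout_sd < 0 || shot_scale < 0)
    stop_dq("wall_sd, readout_sd and shot_scale must be >= 0",
            class = "dq_parameter_error")
  structure(list(group_label = group_label, wall_mean = wall_mean,
                 wall_sd = wall_sd, cytoplasm_frac = cytoplasm_frac,
                 background_frac = background_frac, vessel_frac = vessel_frac,
                 adipose_frac = adipose_frac, connective_frac = connective_frac,
                 readout_sd = readout_sd, shot_scale = shot_scale),
            class = "group_intensity_params")
}

# Noiseless per-pixel intensity at the emission-peak window for one channel:
# wall segments get independent draws per unordered fibre pair, interiors a
# per-fibre cytoplasm level, confounder classes fixed fractions.
channel_value_image <- function(geometry, params) {
  g <- geometry
  val <- matrix(params$background_frac * params$wall_mean, g$rows, g$cols)
  lab <- g$label_image
  val[lab > 0] <- params$cytoplasm_frac * params$wall_mean
  val[lab == -2L] <- params$vessel_frac * params$wall_mean
  val[lab == -3L] <- params$adipose_frac * params$wall_mean
  val[lab == -4L] <- params$connective_frac * params$wall_mean
  patches <- g$wall_patch[g$wall_mask]
  patch_vals <- pmax(0, rnorm(max(patches), params$wall_mean, params$wall_sd))
  val[g$wall_mask] <- patch_vals[patches]
  val
}

render_channel <- function(value_img, response, bleed_img = NULL,
                           bleed_response = NULL, bleed_coef = 0,
                           autofluorescence_au = 0, readout_sd = 10,
                           shot_scale = 2, bit_depth = 12L) {
  R <- nrow(value_img); C <- ncol(value_img); L <- length(response)
  ceiling_au <- 2^bit_depth - 1
  cube <- array(0, c(R, C, L))
  for (k in seq_len(L)) {
    clean <- value_img * response[k] + autofluorescence_au
    if (bleed_coef > 0 && !is.null(bleed_img))
      clean <- clean + bleed_coef * bleed_img * bleed_response[k]
    if (readout_sd > 0 || shot_scale > 0) {
      sdv <- sqrt(readout_sd^2 + shot_scale * clean)
      clean <- clean + rnorm(length(clean), 0, sdv)
    }
    cube[, , k] <- pmin(pmax(round(clean), 0), ceiling_au)
  }
  cube
}

#' Render a two-channel synthetic spectral field
#'
#' Produces co-registered beta-spectrin (membrane guide) and dystrophin
#' lambda stacks over a ground-truth geometry. Slice `k` of a channel is the
#' quantized sum of the class intensity scaled by the fluorophore's window
#' response, an optional flat autofluorescence term, an optional linear
#' bleed-through term from the other channel, and Gaussian-approximated shot
#' plus readout noise; values clip at the 12-bit ceiling. Several dystrophin
#' antibodies can be rendered against the same geometry and beta channel by
#' passing a named list of parameter sets.
#'
#' @param geometry A [generate_geometry()] result.
#' @param beta_params,dys_params [group_intensity_params()]; `dys_params` may
#'   be a named list of them (one per antibody).
#' @param beta_axis,dys_axis Wavelength axes for the two channels.
#' @param seed Integer seed (bit-identical output for identical inputs).
#' @param beta_fluor,dys_fluor [fluorophore_model()]s; defaults are
#'   Cy5-like (670 nm) and AF488-like (519 nm) emission peaks.
#' @param autofluorescence_au Flat background added to every window (a.u.).
#' @param bleed_beta_into_dys,bleed_dys_into_beta Linear leakage
#'   coefficients between channels (default 0).
#' @return An object of class `synthetic_field`: `beta_stack`, `dys_stacks`
#'   (named list; `dys_stack` aliases the first), `geometry`, `truth`, `seed`.
#' @export
render_field <- function(geometry, beta_params, dys_params,
                         beta_axis = dysquant::beta_axis(),
                         dys_axis = dysquant::dys_axis(), seed = 1L,
                         beta_fluor = fluorophore_model(670, 22),
                         dys_fluor = fluorophore_model(519, 18),
                         autofluorescence_au = 0,
                         bleed_beta_into_dys = 0, bleed_dys_into_beta = 0) {
  if (inherits(dys_params, "group_intensity_params"))
    dys_params <- list("NCL-Dys1" = dys_params)
  if (is.null(names(dys_params)) || any(names(dys_params) == ""))
    stop_dq("dys_params list must be named by antibody", class = "dq_parameter_error")

  r_beta <- window_response(beta_fluor, beta_axis)
  r_dys <- window_response(dys_fluor, dys_axis)
  r_dys_on_beta <- window_response(dys_fluor, beta_axis, native_axis = dys_axis)
  r_beta_on_dys <- window_response(beta_fluor, dys_axis, native_axis = beta_axis)

  with_seed(seed, {
    beta_img <- channel_value_image(geometry, beta_params)
    dys_imgs <- lapply(dys_params, function(p) channel_value_image(geometry, p))

    beta_cube <- render_channel(beta_img, r_beta,
                                bleed_img = dys_imgs[[1]],
                                bleed_response = r_dys_on_beta,
                                bleed_coef = bleed_dys_into_beta,
                                autofluorescence_au = autofluorescence_au,
                                readout_sd = beta_params$readout_sd,
                                shot_scale = beta_params$shot_scale)
    dys_cubes <- lapply(seq_along(dys_imgs), function(i)
      render_channel(dys_imgs[[i]], r_dys,
                     bleed_img = beta_img,
                     bleed_response = r_beta_on_dys,
                     bleed_coef = bleed_beta_into_dys,
                     autofluorescence_au = autofluorescence_au,
                     readout_sd = dys_params[[i]]$readout_sd,
                     shot_scale = dys_params[[i]]$shot_scale))

    beta_stack <- spectral_stack(beta_cube, beta_axis, excitation_nm = 570,
                                 channel_label = "beta-spectrin")
    dys_stacks <- lapply(seq_along(dys_cubes), function(i)
      spectral_stack(dys_cubes[[i]], dys_axis, excitation_nm = 470,
                     channel_label = names(dys_params)[i]))
    names(dys_stacks) <- names(dys_params)

    peak_k <- which.max(r_dys)
    truth <- list(
      beta = truth_for(beta_params, beta_cube, which.max(r_beta), geometry),
      dys = lapply(seq_along(dys_params), function(i)
        truth_for(dys_params[[i]], dys_cubes[[i]], peak_k, geometry)))
    names(truth$dys) <- names(dys_params)

    structure(list(beta_stack = beta_stack, dys_stacks = dys_stacks,
                   dys_stack = dys_stacks[[1]], geometry = geometry,
                   truth = truth, seed = seed),
              class = "synthetic_field")
  })
}

truth_for <- function(params, cube, peak_k, geometry) {
  wall_at_peak <- cube[, , peak_k][geometry$wall_mask]
  clip_frac <- mean(wall_at_peak >= 4095)
  list(wall_mean = params$wall_mean,
       cytoplasm = params$cytoplasm_frac * params$wall_mean,
       background = params$background_frac * params$wall_mean,
       peak_slice = peak_k,
       clipped_wall_frac = clip_frac,
       clipping_warning = clip_frac > 0.01)
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %dx%d px, %d fibres, antibodies: %s, seed %d\n",
              x$geometry$rows, x$geometry$cols, x$geometry$fibre_count,
              paste(names(x$dys_stacks), collapse = ", "), x$seed))
  invisible(x)
}
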