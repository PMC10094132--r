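# Shared fixtures: small synthetic fields keep unit tests fast; the
# acceptance suite uses full 512 x 512 fields.

tiny_geometry <- function(seed = 1L, n_fibres = 8L, rows = 160L, cols = 160L,
                          ...) {
  generate_geometry(rows = rows, cols = cols, n_fibres = n_fibres,
                    wall_thickness_px = 4L, seed = seed, ...)
}

tiny_field <- function(group = "DMD", seed = 1L, noiseless = FALSE, ...) {
  noise <- if (noiseless) list(readout_sd = 0, shot_scale = 0) else
    list(readout_sd = 10, shot_scale = 2)
  simulate_field(group, seed = seed, rows = 160L, cols = 160L, n_fibres = 8L,
                 noise = noise, ...)
}

# a short wavelength axis for cheap hand-built stacks
small_axis <- function(n = 5L) wavelength_axis(500, 500 + 5 * (n - 1) + 0.1, 5, 8)

# constant-value stack helper
const_stack <- function(value, dims = c(12L, 12L), axis = small_axis()) {
  cube <- array(value, c(dims, length(axis$centers_nm)))
  spectral_stack(cube, axis, excitation_nm = 470)
}

expect_roi_sets_equal <- function(a, b) {
  expect_identical(serialize(a, NULL), serialize(b, NULL))
}
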