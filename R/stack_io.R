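#' Read and write spectral stacks as multi-page TIFF plus JSON sidecar
#'
#' Stacks are stored as one 16-bit TIFF page per wavelength slice (12-bit
#' intensities in 16-bit containers, standard TIFF practice) together with a
#' JSON sidecar `<path>.json` holding the acquisition metadata:
#' `centers_nm`, `step_nm`, `bandwidth_nm`, `excitation_nm`, `pixel_size_um`,
#' `bit_depth` and `channel_label`. `read_stack(write_stack(s, p))` returns a
#' bit-identical cube and axis.
#'
#' @param path TIFF file path (the sidecar lives at `paste0(path, ".json")`).
#' @param channel_label Optional label overriding the sidecar's.
#' @return `read_stack()`: a validated [spectral_stack()].
#' @export
read_stack <- function(path, channel_label = NULL) {
  if (!file.exists(path))
    stop_dq("stack file not found: ", path, class = "dq_io_error")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_dq("missing wavelength-axis sidecar: ", sidecar,
            class = "dq_metadata_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("centers_nm", "step_nm", "bandwidth_nm", "excitation_nm",
            "pixel_size_um", "bit_depth")
  if (!all(need %in% names(meta)))
    stop_dq("sidecar lacks fields: ",
            paste(setdiff(need, names(meta)), collapse = ", "),
            class = "dq_metadata_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop_dq("ragged TIFF pages: slices differ in size", class = "dq_format_error")
  axis <- new_wavelength_axis(meta$centers_nm, meta$step_nm, meta$bandwidth_nm)
  if (length(pages) != length(axis$centers_nm))
    stop_dq("stack has ", length(pages), " pages but the axis lists ",
            length(axis$centers_nm), " centers", class = "dq_metadata_error")
  d <- dim(pages[[1]])
  cube <- array(0, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) cube[, , k] <- round(pages[[k]] * 65535)
  ceiling_au <- 2^meta$bit_depth - 1
  if (max(cube) > ceiling_au)
    stop_dq("intensities exceed the ", meta$bit_depth,
            "-bit ceiling declared in the sidecar", class = "dq_metadata_error")
  spectral_stack(cube, axis, meta$excitation_nm, meta$pixel_size_um,
                 meta$bit_depth,
                 channel_label %||% (meta$channel_label %||% ""))
}

#' @rdname read_stack
#' @param stack A valid [spectral_stack()].
#' @return `write_stack()`: `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "spectral_stack"))
    stop_dq("stack must be a spectral_stack", class = "dq_stack_error")
  pages <- lapply(seq_len(dim(stack$cube)[3]),
                  function(k) stack$cube[, , k] / 65535)
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "deflate")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_dq("cannot write stack: ", path, class = "dq_io_error")
  meta <- list(centers_nm = stack$axis$centers_nm,
               step_nm = stack$axis$step_nm,
               bandwidth_nm = stack$axis$bandwidth_nm,
               excitation_nm = stack$excitation_nm,
               pixel_size_um = stack$pixel_size_um,
               bit_depth = stack$bit_depth,
               channel_label = stack$channel_label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
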