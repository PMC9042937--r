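#' Write / read a compound stack
#'
#' Stacks are serialized with full metadata (pixel pitch, frame rate, and
#' any attached scene truth) to a single self-describing file.
#'
#' @param stack A [compound_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound_stack <- function(stack, path) {
  abort_if(!inherits(stack, "compound_stack"), "`stack` must be a compound_stack.")
  saveRDS(list(data = stack$data, dx = stack$dx, dz = stack$dz,
               frame_rate = stack$frame_rate, truth = attr(stack, "truth")),
          path, version = 3)
  invisible(path)
}

#' @rdname write_compound_stack
#' @export
read_compound_stack <- function(path) {
  x <- readRDS(path)
  out <- compound_stack(x$data, dx = x$dx, dz = x$dz, frame_rate = x$frame_rate)
  attr(out, "truth") <- x$truth
  out
}

#' Write a power-Doppler image as float TIFF with a JSON sidecar
#'
#' The image is stored as 32-bit float TIFF (intensities normalized if
#' requested) and the metadata — pixel pitch, the clutter band used, the
#' achieved blood-to-noise ratio — as `<path>.json`.
#'
#' @param image A `power_doppler` image.
#' @param path TIFF path.
#' @param band Optional [clutter_band()] recorded in the sidecar.
#' @param snr Optional ratio recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_power_doppler <- function(image, path, band = NULL, snr = NULL) {
  abort_if(!inherits(image, "power_doppler"), "`image` must be a power_doppler.")
  tiff::writeTIFF(unclass(image) / max(max(image), 1e-300), path,
                  bits.per.sample = 32L)
  meta <- list(dx_mm = attr(image, "dx"), dz_mm = attr(image, "dz"),
               scale = max(max(image), 1e-300),
               band = if (!is.null(band)) unclass(band),
               snr = snr)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_power_doppler
#' @export
read_power_doppler <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  power_doppler_image(m * meta$scale, dx = meta$dx_mm, dz = meta$dz_mm)
}

#' Write / read a fluorescence z-stack as multi-page TIFF with sidecar
#'
#' Planes are written as one TIFF page each (intensities scaled to `[0, 1]`)
#' and the voxel size plus the scale factor go to `<path>.json`.
#'
#' @param volume A [fluor_volume()].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_fluor_volume <- function(volume, path) {
  abort_if(!inherits(volume, "fluor_volume"), "`volume` must be a fluor_volume.")
  scale <- max(max(volume$intensity), 1e-300)
  pages <- lapply(seq_len(dim(volume$intensity)[3]),
                  function(p) volume$intensity[, , p] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fluor_volume
#' @export
read_fluor_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- pages[[p]] * meta$scale
  fluor_volume(arr, voxel_size = meta$voxel_size_um)
}

#' Write / read a tidy cohort table as CSV
#' @param table Tibble with the cohort columns (see [gen_cohort()]).
#' @param path CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
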