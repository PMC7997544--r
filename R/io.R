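#' Multi-channel image field container
#'
#' A thin container for a calibrated photon-count stack: a 4-D array indexed
#' `[y, x, z, channel]` plus the physical voxel calibration and channel
#' names.
#'
#' @param data 4-D numeric array `[y, x, z, channel]` (3-D and 2-D inputs
#'   are promoted).
#' @param channels Character vector of channel names.
#' @param pixel_size_um Lateral pixel pitch (um/px).
#' @param z_step_um Axial step (um).
#' @return An `ImageField` object.
#' @export
new_image_field <- function(data, channels, pixel_size_um, z_step_um) {
  d <- dim(data) %||% stop("data must be an array")
  if (length(d) == 2) dim(data) <- c(d, 1L, 1L)
  if (length(d) == 3) dim(data) <- c(d, 1L)
  stopifnot(length(dim(data)) == 4, dim(data)[4] == length(channels),
            pixel_size_um > 0, z_step_um > 0)
  structure(list(data = data, channels = channels,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um),
            class = "ImageField")
}

#' @export
print.ImageField <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ImageField: %d x %d px, %d z-plane(s), channels [%s]\n  %.4f um/px, %.3f um z-step\n",
    d[2], d[1], d[3], paste(x$channels, collapse = ", "),
    x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Extract one channel's Z-stack from an ImageField
#'
#' @param field An `ImageField`.
#' @param channel Channel name.
#' @return 3-D array `[y, x, z]`.
#' @export
get_channel <- function(field, channel) {
  stopifnot(inherits(field, "ImageField"))
  ci <- match(channel, field$channels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  out <- field$data[, , , ci]
  if (length(dim(out) %||% 1) < 3) dim(out) <- dim(field$data)[1:3]
  out
}

#' Write an ImageField as multi-page TIFF with JSON sidecar
#'
#' Pages are ordered channel-major (all Z planes of channel 1, then channel
#' 2, ...). Pixel values are stored as 32-bit floats scaled into `[0, 1]`;
#' the scale factor, calibration and channel names go to `<path>.json`.
#'
#' @param field An `ImageField`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(field, path) {
  stopifnot(inherits(field, "ImageField"))
  d <- dim(field$data)
  scale <- max(field$data, 1)
  pages <- list()
  for (ci in seq_len(d[4]))
    for (zi in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- field$data[, , zi, ci] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = field$channels, n_z = d[3],
               pixel_size_um = field$pixel_size_um,
               z_step_um = field$z_step_um, intensity_scale = scale,
               page_order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ImageField written by [write_image()]
#'
#' @param path TIFF path; `<path>.json` must exist and carry
#'   `pixel_size_um`, `z_step_um`, `channels`, `n_z`, `intensity_scale`.
#' @return An `ImageField` in photon units.
#' @export
read_image <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing calibration sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (fld in c("pixel_size_um", "z_step_um", "channels", "n_z",
                "intensity_scale"))
    if (is.null(meta[[fld]]))
      stop("calibration sidecar missing field: ", fld)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_z <- as.integer(meta$n_z)
  n_c <- length(meta$channels)
  if (length(pages) != n_z * n_c)
    stop("page count ", length(pages), " does not match ", n_c,
         " channel(s) x ", n_z, " plane(s)")
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], n_z, n_c))
  k <- 1L
  for (ci in seq_len(n_c))
    for (zi in seq_len(n_z)) {
      arr[, , zi, ci] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  new_image_field(arr, meta$channels, meta$pixel_size_um, meta$z_step_um)
}

#' Write a detection table as CSV (um / photon units)
#'
#' @param table A `detection_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
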