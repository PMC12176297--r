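#' Multi-channel 3D image stack
#'
#' Container for a confocal-like voxel array with anisotropic spacing.
#' Voxels are stored `(z, y, x, channel)` with 0-based physical coordinates:
#' voxel `(i, j, k)` (1-based indices) spans
#' `[(i-1) * dz, i * dz)` along z, and similarly in y and x.
#'
#' @param voxels numeric 4D array `(z, y, x, channel)`, or a 3D array for a
#'   single channel.
#' @param spacing numeric length-3, voxel pitch in micrometres `(dz, dy, dx)`.
#' @param channel_names character vector naming the channels.
#' @return An object of class `xi_stack`: a list with elements `voxels`,
#'   `spacing`, `channel_names`.
#' @examples
#' s <- image_stack(array(0, c(4, 8, 8, 2)), c(0.2, 0.1, 0.1),
#'                  c("dapi", "fish"))
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing = c(0.2, 0.1, 0.1),
                        channel_names = NULL) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a (z, y, x, channel) array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (dz, dy, dx)")
  nc <- dim(voxels)[4]
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names must match the number of channels")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 channel_names = as.character(channel_names)),
            class = "xi_stack")
}

#' @export
print.xi_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<xi_stack> %d x %d x %d voxels (z,y,x), %d channel(s): %s\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  spacing (um): dz=%g dy=%g dx=%g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Stores intensities as 16-bit unsigned TIFF pages (losslessly, for integer
#' intensities up to 65535) in z-major, channel-minor page order, with a
#' `<path>.json` sidecar recording dimensions, spacing and channel names.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "xi_stack"))
  d <- dim(stack$voxels)
  if (max(stack$voxels) > 65535 || min(stack$voxels) < 0)
    stop("intensities must lie in [0, 65535] for 16-bit storage")
  pages <- vector("list", d[1] * d[4])
  i <- 0L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      i <- i + 1L
      pages[[i]] <- stack$voxels[z, , , ch] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(dim = d, spacing = stack$spacing,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != d[1] * d[4]) stop("page count does not match sidecar")
  vox <- array(0, d)
  i <- 0L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      i <- i + 1L
      vox[z, , , ch] <- round(pages[[i]] * 65535)
    }
  }
  image_stack(vox, meta$spacing, meta$channel_names)
}
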