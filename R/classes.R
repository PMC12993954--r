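#' Binarized timelapse movie
#'
#' Container for a 2D+T boolean movie — the substrate of the surveillance and
#' chemotaxis metrics. Frames are stored as a `Y x X x T` logical array
#' (`movie$frames[, , t]` is the binarized frame at timepoint `t`), with
#' physical calibration attached.
#'
#' Pixel coordinates used throughout the package are 0-based with
#' `x = column`, `y = row` and the origin at the top-left pixel centre; all
#' physical distances are in micrometres via `pixel_size`.
#'
#' @param frames logical array `Y x X x T` (a single logical matrix is
#'   accepted and treated as one frame).
#' @param pixel_size pixel size in micrometres per pixel.
#' @param frame_interval time between consecutive frames in seconds.
#' @return An object of class `binary_movie` with elements `frames`,
#'   `pixel_size` and `frame_interval`.
#' @examples
#' f <- array(FALSE, c(8, 8, 2)); f[3:5, 3:5, ] <- TRUE
#' binary_movie(f, pixel_size = 0.25, frame_interval = 30)
#' @export
binary_movie <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a Y x X x T array")
  if (!is.logical(frames))
    stop("'frames' must be logical (binarized); got ", typeof(frames))
  stopifnot_scalar(pixel_size, "pixel_size")
  stopifnot_scalar(frame_interval, "frame_interval")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "binary_movie")
}

#' @export
print.binary_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<binary_movie> %d x %d px, %d frames, %.3g um/px, %g s/frame\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  cat(sprintf("  foreground fraction (frame 1): %.4f\n",
              mean(x$frames[, , 1])))
  invisible(x)
}

#' @export
dim.binary_movie <- function(x) dim(x$frames)

#' 4D intensity timelapse stack
#'
#' Raw (or embedded synthetic) multi-slice intensity movie with physical
#' calibration, stored as a `Y x X x Z x T` numeric array.
#'
#' @param data numeric array `Y x X x Z x T`.
#' @param pixel_size lateral pixel size, micrometres per pixel.
#' @param z_step axial spacing between optical sections, micrometres.
#' @param frame_interval time between frames, seconds.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, pixel_size, z_step, frame_interval) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a Y x X x Z x T array")
  stopifnot_scalar(pixel_size, "pixel_size")
  stopifnot_scalar(z_step, "z_step")
  stopifnot_scalar(frame_interval, "frame_interval")
  if (dim(data)[4] < 1L) stop("stack must contain at least one frame")
  structure(
    list(data = data, pixel_size = pixel_size, z_step = z_step,
         frame_interval = frame_interval),
    class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<timelapse_stack> %d x %d px, %d z, %d frames (%.3g um/px, %g um z, %g s)\n",
    d[1], d[2], d[3], d[4], x$pixel_size, x$z_step, x$frame_interval))
  invisible(x)
}

#' Co-registered single-cell organelle volumes
#'
#' One 3D frame holding a cell mask plus lysosome-marker and
#' presynaptic-puncta channels, for engulfment scoring. Arrays are
#' `Z x Y x X`; `voxel_size` is `(z, y, x)` in micrometres, so voxels may be
#' anisotropic (volumes are computed in um^3, while connectivity stays
#' lattice-based).
#'
#' @param cell_mask logical array `Z x Y x X`, the cell volume.
#' @param lysosome_channel numeric or logical array, same shape.
#' @param puncta_channel numeric or logical array, same shape.
#' @param voxel_size numeric length-3, micrometres per voxel `(z, y, x)`.
#' @return An object of class `organelle_volumes`.
#' @export
organelle_volumes <- function(cell_mask, lysosome_channel, puncta_channel,
                              voxel_size) {
  dims <- dim(cell_mask)
  if (is.null(dims) || length(dims) != 3L)
    stop("'cell_mask' must be a Z x Y x X array")
  if (!is.logical(cell_mask)) stop("'cell_mask' must be logical")
  if (!identical(dim(lysosome_channel), dims) ||
      !identical(dim(puncta_channel), dims))
    stop("all channels must share the cell_mask dimensions")
  if (!any(cell_mask)) stop("'cell_mask' is empty")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be three positive values (z, y, x) in um")
  structure(
    list(cell_mask = cell_mask, lysosome_channel = lysosome_channel,
         puncta_channel = puncta_channel,
         voxel_size = as.numeric(voxel_size)),
    class = "organelle_volumes")
}

#' @export
print.organelle_volumes <- function(x, ...) {
  d <- dim(x$cell_mask)
  cat(sprintf(
    "<organelle_volumes> %d x %d x %d voxels (%.3g x %.3g x %.3g um), cell %d voxels\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    sum(x$cell_mask)))
  invisible(x)
}

#' Write / read a binary movie as multi-page TIFF with JSON sidecar
#'
#' Movies are stored as 8-bit multi-page TIFF (foreground 255, background 0),
#' one page per frame, with calibration (`pixel_size`, `frame_interval` and
#' any extra metadata) in a JSON sidecar next to the TIFF
#' (`<path>.json` by default).
#'
#' @param movie a [binary_movie()].
#' @param path output TIFF path.
#' @param sidecar path for the JSON sidecar; default `paste0(path, ".json")`.
#' @param metadata optional named list merged into the sidecar.
#' @return `write_binary_movie()` returns `path` invisibly;
#'   `read_binary_movie()` returns a [binary_movie()].
#' @export
write_binary_movie <- function(movie, path, sidecar = paste0(path, ".json"),
                               metadata = list()) {
  stopifnot(inherits(movie, "binary_movie"))
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(t) movie$frames[, , t] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- c(list(pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval), metadata)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binary_movie
#' @export
read_binary_movie <- function(path, sidecar = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(FALSE, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] > 0.5
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  binary_movie(frames, pixel_size = meta$pixel_size,
               frame_interval = meta$frame_interval)
}

#' Write / read an intensity stack as multi-page TIFF with JSON sidecar
#'
#' Pages are ordered z-fastest (all z planes of frame 1, then frame 2, ...).
#' Intensities are stored as 16-bit after scaling to the stack maximum; the
#' scale factor is recorded in the sidecar and undone on read.
#'
#' @param stack a [timelapse_stack()].
#' @param path output TIFF path.
#' @param sidecar path for the JSON sidecar.
#' @return `write_timelapse_stack()` returns `path` invisibly;
#'   `read_timelapse_stack()` returns a [timelapse_stack()].
#' @export
write_timelapse_stack <- function(stack, path,
                                  sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[k]] <- stack$data[, , z, t] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size = stack$pixel_size, z_step = stack$z_step,
         frame_interval = stack$frame_interval, n_z = d[3], n_frames = d[4],
         intensity_scale = scale),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timelapse_stack
#' @export
read_timelapse_stack <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- meta$n_z; nt <- meta$n_frames
  if (length(pages) != nz * nt)
    stop("page count does not match sidecar n_z * n_frames")
  data <- array(0, c(dim(pages[[1]]), nz, nt))
  k <- 1L
  for (t in seq_len(nt)) for (z in seq_len(nz)) {
    data[, , z, t] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  timelapse_stack(data, meta$pixel_size, meta$z_step, meta$frame_interval)
}
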