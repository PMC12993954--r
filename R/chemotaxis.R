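# Concentric-ring / 32-sector lesion-front tracking.

#' Polar grid configuration for front tracking
#'
#' The area around the lesion centre is divided into concentric rings of
#' `ring_width` um and `n_sectors` radial sectors, creating `n_sectors`
#' patches between every two consecutive rings. The front in a sector is the
#' innermost patch holding strictly more than `min_patch_pixels` foreground
#' pixels.
#'
#' @param lesion_center `(x, y)` 0-based pixel coordinates of the lesion
#'   centre.
#' @param ring_width ring width, um.
#' @param n_sectors number of angular sectors.
#' @param min_patch_pixels front qualification count; a patch qualifies when
#'   its foreground count is strictly greater than this.
#' @param max_radius outer tracking radius, um; `NULL` (default) uses the
#'   largest radius fully inside the image.
#' @param report_at where the front distance is reported within the
#'   qualifying patch: `"midpoint"` (default; quantization error symmetric,
#'   +/- `ring_width / 2`) or `"inner"` (ring inner radius).
#' @return A `polar_grid_config` list.
#' @export
polar_grid_config <- function(lesion_center,
                              ring_width = 2,
                              n_sectors = 32L,
                              min_patch_pixels = 10L,
                              max_radius = NULL,
                              report_at = c("midpoint", "inner")) {
  if (ring_width <= 0) stop("'ring_width' must be > 0")
  if (n_sectors < 1L) stop("'n_sectors' must be >= 1")
  if (min_patch_pixels < 0L) stop("'min_patch_pixels' must be >= 0")
  report_at <- match.arg(report_at)
  structure(as.list(environment()), class = "polar_grid_config")
}

#' Build the (ring, sector) patch map
#'
#' Assigns every pixel with centre distance strictly less than `max_radius`
#' from the lesion centre to exactly one patch. Ring `k` (0-based) covers
#' radii `[k * w, (k + 1) * w)`; sector `j` (0-based) covers angles
#' `[j * 2 * pi / n, (j + 1) * 2 * pi / n)` measured counterclockwise from
#' the +x axis in array coordinates (y increasing downward; the angular
#' origin and direction are fixed only for determinism — rotationally
#' summarized outputs do not depend on them). The pixel exactly at the
#' centre has radius 0 and angle 0, so it lands in ring 0, sector 0.
#'
#' @param grid a [polar_grid_config()].
#' @param image_shape integer `(H, W)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `polar_patches`: integer matrices `ring` and
#'   `sector` (`NA` outside `max_radius`), plus `n_rings`, `max_radius` and
#'   the generating config.
#' @export
build_polar_patches <- function(grid, image_shape, pixel_size) {
  stopifnot(inherits(grid, "polar_grid_config"))
  H <- image_shape[1]; W <- image_shape[2]
  cx <- grid$lesion_center[1]; cy <- grid$lesion_center[2]
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
    stop("lesion_center lies outside the image")
  max_radius <- grid$max_radius
  if (is.null(max_radius))
    max_radius <- min(cx, W - 1 - cx, cy, H - 1 - cy) * pixel_size
  if (max_radius <= 0) stop("'max_radius' must be > 0")
  x <- matrix(rep(0:(W - 1), each = H), H)
  y <- matrix(rep(0:(H - 1), times = W), H)
  r_um <- sqrt((x - cx)^2 + (y - cy)^2) * pixel_size
  ang <- atan2(y - cy, x - cx) %% (2 * pi)
  ring <- floor(r_um / grid$ring_width)
  sector <- pmin(floor(ang / (2 * pi / grid$n_sectors)),
                 grid$n_sectors - 1L)
  inside <- r_um < max_radius
  ring[!inside] <- NA
  sector[!inside] <- NA
  storage.mode(ring) <- "integer"
  storage.mode(sector) <- "integer"
  structure(
    list(ring = ring, sector = sector,
         n_rings = as.integer(ceiling(max_radius / grid$ring_width)),
         max_radius = max_radius, pixel_size = pixel_size, grid = grid),
    class = "polar_patches")
}

#' Per-sector distance to the process front
#'
#' For each sector, rings are scanned outward from ring 0; the front is the
#' first patch whose foreground pixel count strictly exceeds
#' `min_patch_pixels`. The reported distance is the patch radial midpoint
#' (`(k + 0.5) * ring_width`) by default, or the inner edge if the grid was
#' built with `report_at = "inner"`. Sectors in which no patch qualifies are
#' `NA`.
#'
#' @param frame logical matrix `Y x X`.
#' @param patches a [build_polar_patches()] result matching the frame shape.
#' @return Numeric vector of `n_sectors` distances in um (`NA` where
#'   undefined).
#' @export
front_distance <- function(frame, patches) {
  stopifnot(inherits(patches, "polar_patches"), is.logical(frame))
  if (!identical(dim(frame), dim(patches$ring)))
    stop("frame shape does not match the patch map")
  g <- patches$grid
  n <- g$n_sectors
  fg <- which(frame & !is.na(patches$ring))
  out <- rep(NA_real_, n)
  if (length(fg) == 0L) return(out)
  code <- patches$ring[fg] * n + patches$sector[fg]   # 0-based patch id
  counts <- tabulate(code + 1L, nbins = patches$n_rings * n)
  qual <- counts > g$min_patch_pixels
  for (j in seq_len(n)) {
    ids <- (seq_len(patches$n_rings) - 1L) * n + (j - 1L)
    k <- which(qual[ids + 1L])
    if (length(k)) {
      ring0 <- k[1] - 1L
      out[j] <- if (g$report_at == "midpoint")
        (ring0 + 0.5) * g$ring_width else ring0 * g$ring_width
    }
  }
  out
}

#' Area enclosed by the process front
#'
#' The per-sector front points are placed at sector mid-angles and joined
#' into a polygon; the area is computed with the shoelace formula. Sectors
#' with an undefined front are assigned `max_radius` before polygon
#' construction (rather than being dropped, which would leave the polygon
#' ill-defined), and the number of substituted sectors is reported so
#' downstream users can filter.
#'
#' @param distances numeric vector of `n_sectors` front distances in um
#'   (`NA` = undefined).
#' @param patches a [build_polar_patches()] result (provides `max_radius`
#'   and the sector count).
#' @return A list with `area` (um^2) and `n_substituted`.
#' @examples
#' # all distances R: regular n-gon, area (n/2) R^2 sin(2 pi / n)
#' @export
enclosed_area <- function(distances, patches) {
  stopifnot(inherits(patches, "polar_patches"))
  n <- patches$grid$n_sectors
  if (length(distances) != n)
    stop("'distances' must have one entry per sector")
  n_sub <- sum(is.na(distances))
  d <- ifelse(is.na(distances), patches$max_radius, distances)
  theta <- (seq_len(n) - 0.5) * 2 * pi / n
  x <- d * cos(theta); y <- d * sin(theta)
  j <- c(2:n, 1L)
  area <- abs(sum(x * y[j] - x[j] * y)) / 2
  list(area = area, n_substituted = n_sub)
}

#' Front profile and convergence summary over a movie
#'
#' Computes per-frame sector front distances and enclosed areas, the
#' normalized area curve `area(t) / area(first frame)`, and a summary
#' convergence rate: the least-squares slope of the normalized curve against
#' time in minutes over `window` (default all frames). Converging fronts
#' give negative rates.
#'
#' @param movie a [binary_movie()].
#' @param grid a [polar_grid_config()].
#' @param window optional integer vector of frame indices for the rate fit.
#' @return An object of class `front_profile`: `distance` (`T x n_sectors`
#'   matrix, um), `enclosed_area` and `normalized_area` (length `T`),
#'   `n_substituted` (per frame), `rate_per_min`, `patches`.
#' @export
convergence_curve <- function(movie, grid, window = NULL) {
  stopifnot(inherits(movie, "binary_movie"),
            inherits(grid, "polar_grid_config"))
  d <- dim(movie$frames)
  patches <- build_polar_patches(grid, d[1:2], movie$pixel_size)
  T_ <- d[3]
  dist <- matrix(NA_real_, T_, grid$n_sectors)
  area <- nsub <- numeric(T_)
  for (t in seq_len(T_)) {
    dist[t, ] <- front_distance(movie$frames[, , t], patches)
    ea <- enclosed_area(dist[t, ], patches)
    area[t] <- ea$area
    nsub[t] <- ea$n_substituted
  }
  norm <- if (area[1] > 0) area / area[1] else rep(NA_real_, T_)
  if (is.null(window)) window <- seq_len(T_)
  tmin <- (window - 1) * movie$frame_interval / 60
  rate <- if (length(window) >= 2L && all(is.finite(norm[window])))
    unname(coef(lm(norm[window] ~ tmin))[2]) else NA_real_
  structure(
    list(distance = dist, enclosed_area = area, normalized_area = norm,
         n_substituted = nsub, rate_per_min = rate, patches = patches,
         frame_interval = movie$frame_interval),
    class = "front_profile")
}

#' @export
print.front_profile <- function(x, ...) {
  cat(sprintf(
    "<front_profile> %d frames x %d sectors; normalized-area rate %.4f / min\n",
    nrow(x$distance), ncol(x$distance), x$rate_per_min))
  invisible(x)
}

#' Long-format front table
#'
#' @param profile a [convergence_curve()] result.
#' @return data.frame with columns `frame`, `sector`, `distance_um`,
#'   `defined`.
#' @export
front_table <- function(profile) {
  stopifnot(inherits(profile, "front_profile"))
  T_ <- nrow(profile$distance); n <- ncol(profile$distance)
  data.frame(frame = rep(seq_len(T_), each = n),
             sector = rep(seq_len(n) - 1L, times = T_),
             distance_um = as.vector(t(profile$distance)),
             defined = !is.na(as.vector(t(profile$distance))))
}
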