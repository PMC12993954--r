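# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that identical
# config + seed gives bit-identical output regardless of ambient RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Otsu's threshold on a numeric vector: maximizes between-class variance of
# the binarization over a fixed-width histogram. Returns a threshold value;
# pixels strictly above it are foreground.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("otsu_threshold: no finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  mids <- (head(breaks, -1L) + tail(breaks, -1L)) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  mu0 <- cumsum(h * mids) / pmax(w0, 1)
  mu1 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w1, 1)
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  breaks[which.max(between) + 1L]
}

# Integer offsets of a discrete disc: all (dy, dx) with dy^2 + dx^2 <= r^2.
disc_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Set pixels within `halfw` (px) of the segment (x0,y0)-(x1,y1) in a logical
# Y x X matrix. Coordinates are 0-based pixel centres, x = column, y = row.
raster_segment <- function(mask, x0, y0, x1, y1, halfw) {
  H <- nrow(mask); W <- ncol(mask)
  xmin <- max(0L, floor(min(x0, x1) - halfw))
  xmax <- min(W - 1L, ceiling(max(x0, x1) + halfw))
  ymin <- max(0L, floor(min(y0, y1) - halfw))
  ymax <- min(H - 1L, ceiling(max(y0, y1) + halfw))
  if (xmin > xmax || ymin > ymax) return(mask)
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  tt <- if (L2 > 0) pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / L2)) else 0
  d2 <- (px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2
  sel <- d2 <= halfw^2
  if (any(sel)) mask[cbind(py[sel] + 1L, px[sel] + 1L)] <- TRUE
  mask
}

# Filled disc into a logical matrix (0-based centre coordinates).
raster_disc <- function(mask, xc, yc, radius_px) {
  raster_segment(mask, xc, yc, xc, yc, radius_px)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
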