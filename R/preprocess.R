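# Preprocessing chain applied to raw movies before metric extraction.
# Fixed order: register -> background subtract -> max filter ->
# bleach correct -> project -> threshold.

#' Preprocessing configuration
#'
#' @param background_radius rolling-ball structuring radius, px.
#' @param max_filter_radius maximum-filter disc radius, px; 0 disables.
#' @param registration apply XY translation registration to frame 1?
#' @param bleach_correction apply bleach correction?
#' @param bleach_method `"ratio"` (each frame rescaled so its mean matches
#'   frame 1) or `"exponential"` (log-linear fit of the per-frame mean
#'   inverted).
#' @param threshold numeric binarization threshold, or `"auto"` to use
#'   Otsu's criterion on the first-frame maximum-intensity projection (the
#'   realized value is recorded in the run log either way).
#' @param drop_extreme_z number of z planes dropped from each end of the
#'   stack before projection.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(background_radius = 50L,
                              max_filter_radius = 2L,
                              registration = TRUE,
                              bleach_correction = TRUE,
                              bleach_method = c("ratio", "exponential"),
                              threshold = "auto",
                              drop_extreme_z = 0L) {
  if (background_radius < 1L) stop("'background_radius' must be >= 1")
  if (max_filter_radius < 0L) stop("'max_filter_radius' must be >= 0")
  bleach_method <- match.arg(bleach_method)
  if (!identical(threshold, "auto")) {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      stop("'threshold' must be a numeric value or \"auto\"")
  }
  structure(as.list(environment()), class = "preprocess_config")
}

# integer translation with zero fill; m numeric matrix, shift by (dy, dx)
shift_matrix <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  sy <- max(1, 1 + dy):min(H, H + dy)
  sx <- max(1, 1 + dx):min(W, W + dx)
  if (length(sy) == 0L || length(sx) == 0L) return(out)
  out[sy, sx] <- m[sy - dy, sx - dx]
  out
}

#' Translation-only XY registration to the first frame
#'
#' Estimates, for every frame, the integer translation maximizing the
#' phase correlation with the first frame, and applies the correcting shift
#' (out-of-frame regions zero-filled). Rotation and scale are out of scope:
#' slice drift at this magnification is translational.
#'
#' @param movie numeric array `Y x X x T`, `T >= 2`.
#' @return A list with `movie` (registered array) and `shifts` (`T x 2`
#'   matrix of applied `(dy, dx)` corrections; frame 1 is always `(0, 0)`).
#' @examples
#' m <- array(0, c(32, 32, 2)); m[10:14, 10:14, 1] <- 1
#' m[, , 2] <- microdyn:::shift_matrix(m[, , 1], 3, -2)
#' register_xy(m)$shifts
#' @export
register_xy <- function(movie) {
  d <- dim(movie)
  if (length(d) != 3L || d[3] < 2L)
    stop("'movie' must be a Y x X x T array with T >= 2")
  ref <- movie[, , 1]
  Fr <- fft(ref)
  shifts <- matrix(0L, d[3], 2L, dimnames = list(NULL, c("dy", "dx")))
  out <- movie
  for (t in 2:d[3]) {
    fr <- movie[, , t]
    if (all(fr == 0)) {
      warning("frame ", t, " is all zero; shift set to (0, 0)")
      next
    }
    Ft <- fft(fr)
    R <- Fr * Conj(Ft)
    denom <- Mod(R)
    denom[denom < 1e-12] <- 1e-12
    corr <- Re(fft(R / denom, inverse = TRUE))
    p <- which.max(corr)
    py <- (p - 1L) %% d[1]
    px <- (p - 1L) %/% d[1]
    dy <- if (py > d[1] / 2) py - d[1] else py
    dx <- if (px > d[2] / 2) px - d[2] else px
    shifts[t, ] <- c(dy, dx)
    if (dy != 0 || dx != 0) out[, , t] <- shift_matrix(fr, dy, dx)
  }
  list(movie = out, shifts = shifts)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of
#' the frame with a disc structuring element of the given radius, and
#' subtracts it. The opening is computed on an edge-replicated padding so a
#' constant image maps to zero everywhere. Output is nonnegative and never
#' exceeds the input.
#'
#' @param frame numeric matrix `Y x X`.
#' @param radius structuring-element radius, px.
#' @return Background-subtracted matrix.
#' @export
subtract_background <- function(frame, radius = 50L) {
  stopifnot(is.matrix(frame), radius >= 1)
  r <- as.integer(ceiling(radius))
  H <- nrow(frame); W <- ncol(frame)
  pad <- matrix(0, H + 2L * r, W + 2L * r)
  pad[r + (1:H), r + (1:W)] <- frame
  # edge replication
  pad[1:r, ] <- pad[rep(r + 1L, r), ]
  pad[(H + r + 1L):(H + 2L * r), ] <- pad[rep(H + r, r), ]
  pad[, 1:r] <- pad[, rep(r + 1L, r)]
  pad[, (W + r + 1L):(W + 2L * r)] <- pad[, rep(W + r, r)]
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  # EBImage grayscale morphology assumes intensities in [0, 1]: rescale
  rng <- range(pad)
  if (rng[2] > rng[1]) {
    pad01 <- (pad - rng[1]) / (rng[2] - rng[1])
    bg <- EBImage::opening(pad01, brush) * (rng[2] - rng[1]) + rng[1]
  } else {
    bg <- pad
  }
  bg <- bg[r + (1:H), r + (1:W)]
  pmax(frame - pmin(bg, frame), 0)
}

#' Maximum (grayscale dilation) filter with a disc footprint
#'
#' The footprint is the discrete disc of all integer offsets `(dy, dx)` with
#' `dy^2 + dx^2 <= radius^2` (13 pixels at radius 2). Pixels outside the
#' image do not contribute, so a constant image is unchanged. Output is
#' pointwise `>=` input.
#'
#' @param frame numeric matrix.
#' @param radius disc radius, px; 0 returns the input.
#' @return Filtered matrix.
#' @export
max_filter <- function(frame, radius = 2L) {
  stopifnot(is.matrix(frame), radius >= 0)
  if (radius == 0) return(frame)
  offs <- disc_offsets(radius)
  r <- as.integer(ceiling(radius))
  H <- nrow(frame); W <- ncol(frame)
  pad <- matrix(-Inf, H + 2L * r, W + 2L * r)
  pad[r + (1:H), r + (1:W)] <- frame
  out <- matrix(-Inf, H, W)
  for (k in seq_len(nrow(offs)))
    out <- pmax(out, pad[r + offs$dy[k] + (1:H), r + offs$dx[k] + (1:W)])
  out
}

# max filter for logical masks (used when comparing recovered masks to
# ground truth under the documented chain)
max_filter_mask <- function(mask, radius = 2L) {
  if (radius == 0) return(mask)
  max_filter(mask * 1, radius) > 0.5
}

#' Bleach correction of a movie
#'
#' `"ratio"` rescales every frame so its mean intensity equals the first
#' frame's mean (the exact inverse of any per-frame multiplicative decay).
#' `"exponential"` fits `log(mean) ~ frame` by least squares and divides each
#' frame by the fitted relative decay, which is robust when single frames
#' have outlying means.
#'
#' @param movie numeric array `Y x X x T`.
#' @param method `"ratio"` or `"exponential"`.
#' @return Corrected array; the first frame is unchanged under `"ratio"`.
#' @export
bleach_correct <- function(movie, method = c("ratio", "exponential")) {
  method <- match.arg(method)
  d <- dim(movie)
  stopifnot(length(d) == 3L)
  means <- apply(movie, 3, mean)
  if (any(means <= 0)) {
    warning("frame(s) with nonpositive mean; left unscaled")
    means[means <= 0] <- NA
  }
  gain <- if (method == "ratio") {
    means[1] / means
  } else {
    t0 <- seq_len(d[3])
    fit <- lm(log(means) ~ t0)
    pred <- exp(predict(fit, data.frame(t0 = t0)))
    pred[1] / pred
  }
  gain[!is.finite(gain)] <- 1
  out <- movie
  for (t in seq_len(d[3])) out[, , t] <- movie[, , t] * gain[t]
  out
}

#' Maximum-intensity projection and thresholding of a stack
#'
#' Projects each frame along z (after optionally dropping `drop_extreme_z`
#' planes from each end of the stack) and binarizes at a fixed threshold.
#' `"auto"` derives a single value from the first-frame MIP by Otsu's
#' criterion and applies it to all frames; pixels strictly above the
#' threshold are foreground.
#'
#' @param stack a [timelapse_stack()].
#' @param cfg a [preprocess_config()]; only `threshold` and
#'   `drop_extreme_z` are used here.
#' @return A list with `movie` (a [binary_movie()]) and `threshold`
#'   (the realized numeric value).
#' @export
project_and_threshold <- function(stack, cfg = preprocess_config()) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  keep <- seq_len(d[3])
  if (cfg$drop_extreme_z > 0L) {
    if (2L * cfg$drop_extreme_z >= d[3])
      stop("'drop_extreme_z' would remove every z plane")
    keep <- (cfg$drop_extreme_z + 1L):(d[3] - cfg$drop_extreme_z)
  }
  mips <- array(0, c(d[1], d[2], d[4]))
  for (t in seq_len(d[4]))
    mips[, , t] <- apply(stack$data[, , keep, t, drop = FALSE], c(1, 2), max)
  thr <- if (identical(cfg$threshold, "auto"))
    otsu_threshold(mips[, , 1]) else cfg$threshold
  frames <- mips > thr
  fg <- apply(frames, 3, sum)
  if (all(fg == 0L))
    stop("threshold ", signif(thr, 4),
         " yields empty foreground on every frame (first offending frame: 1)")
  list(movie = binary_movie(frames, stack$pixel_size, stack$frame_interval),
       threshold = thr)
}

#' Full preprocessing chain: raw stack to binarized movie
#'
#' Runs the fixed, logged order: XY registration (estimated on per-frame
#' MIPs, applied to every z plane) -> rolling-ball background subtraction ->
#' maximum filtering -> 3D bleach correction (per-frame volume means) ->
#' maximum-intensity projection -> thresholding. All steps preserve array
#' shape (except explicit z-plane dropping) and physical metadata.
#'
#' @param stack a [timelapse_stack()].
#' @param cfg a [preprocess_config()].
#' @return A list with `movie` (a [binary_movie()]) and `log` — a named list
#'   recording every parameter, the applied shifts, and the realized
#'   threshold.
#' @export
preprocess_movie <- function(stack, cfg = preprocess_config()) {
  stopifnot(inherits(stack, "timelapse_stack"),
            inherits(cfg, "preprocess_config"))
  d <- dim(stack$data)
  data <- stack$data
  shifts <- matrix(0L, d[4], 2L, dimnames = list(NULL, c("dy", "dx")))
  if (cfg$registration && d[4] >= 2L) {
    mips <- array(0, c(d[1], d[2], d[4]))
    for (t in seq_len(d[4]))
      mips[, , t] <- apply(data[, , , t, drop = FALSE], c(1, 2), max)
    reg <- register_xy(mips)
    shifts <- reg$shifts
    for (t in seq_len(d[4]))
      if (any(shifts[t, ] != 0L))
        for (z in seq_len(d[3]))
          data[, , z, t] <- shift_matrix(data[, , z, t],
                                         shifts[t, 1], shifts[t, 2])
  }
  for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
    fr <- subtract_background(data[, , z, t], cfg$background_radius)
    if (cfg$max_filter_radius > 0L)
      fr <- max_filter(fr, cfg$max_filter_radius)
    data[, , z, t] <- fr
  }
  if (cfg$bleach_correction && d[4] >= 2L) {
    flat <- array(data, c(d[1], d[2] * d[3], d[4]))
    flat <- bleach_correct(flat, cfg$bleach_method)
    data <- array(flat, d)
  }
  corrected <- timelapse_stack(data, stack$pixel_size, stack$z_step,
                               stack$frame_interval)
  pt <- project_and_threshold(corrected, cfg)
  log <- list(order = paste("register", "subtract_background", "max_filter",
                            "bleach_correct", "project", "threshold",
                            sep = " -> "),
              background_radius = cfg$background_radius,
              max_filter_radius = cfg$max_filter_radius,
              registration = cfg$registration,
              bleach_correction = cfg$bleach_correction,
              bleach_method = cfg$bleach_method,
              drop_extreme_z = cfg$drop_extreme_z,
              threshold_config = cfg$threshold,
              threshold_realized = pt$threshold,
              shifts = shifts)
  list(movie = pt$movie, log = log)
}
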