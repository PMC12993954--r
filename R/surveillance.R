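# Surveillance index and territory area from binarized single-cell movies.

#' Surveillance index of a binarized movie
#'
#' Starting with the second frame, each binarized frame \eqn{F_t} is
#' compared with the preceding frame \eqn{F_{t-1}}: pixels present only in
#' \eqn{F_t} are process extensions (PE), pixels present only in
#' \eqn{F_{t-1}} are process retractions (PR). The surveillance index at
#' each timepoint is PE + PR (the symmetric-difference pixel count), and the
#' per-cell summary is the mean over all `T - 1` frame pairs, with no
#' trimming and no connectivity or size filtering of the changed pixels.
#'
#' The primary unit is pixels per frame interval. When the frame interval is
#' not 30 s, the result additionally carries the value rescaled to pixels
#' per 30 s (`mean_index_per_30s`), so movies taken at other cadences remain
#' comparable; both values are reported.
#'
#' @param movie a [binary_movie()] with at least 2 frames.
#' @return An object of class `surveillance_result`: `pe_counts`,
#'   `pr_counts`, `index_per_frame` (all length `T - 1`), `mean_index`,
#'   `mean_index_per_30s`, `frame_interval`.
#' @examples
#' f <- array(FALSE, c(8, 8, 2))
#' f[1:2, 1:4, 1] <- TRUE       # 8 px, all removed in frame 2
#' f[5:6, 1:3, 2] <- TRUE       # 6 px added
#' surveillance_index(binary_movie(f, 0.25, 30))
#' @export
surveillance_index <- function(movie) {
  stopifnot(inherits(movie, "binary_movie"))
  f <- movie$frames
  if (!is.logical(f)) stop("movie frames must be logical")
  T_ <- dim(f)[3]
  if (T_ < 2L) stop("surveillance index needs at least 2 frames")
  pe <- pr <- integer(T_ - 1L)
  for (t in 2:T_) {
    pe[t - 1L] <- sum(f[, , t] & !f[, , t - 1L])
    pr[t - 1L] <- sum(!f[, , t] & f[, , t - 1L])
  }
  idx <- pe + pr
  mean_index <- mean(idx)
  structure(
    list(pe_counts = pe, pr_counts = pr, index_per_frame = idx,
         mean_index = mean_index,
         mean_index_per_30s = mean_index * 30 / movie$frame_interval,
         frame_interval = movie$frame_interval),
    class = "surveillance_result")
}

#' @export
print.surveillance_result <- function(x, ...) {
  cat(sprintf(
    "<surveillance_result> %d frame pairs, mean index %.2f px per %g s",
    length(x$index_per_frame), x$mean_index, x$frame_interval))
  if (x$frame_interval != 30)
    cat(sprintf(" (%.2f px per 30 s)", x$mean_index_per_30s))
  cat("\n")
  invisible(x)
}

#' Territory area occupied by the cell
#'
#' Foreground area of the first frame of the binarized movie, in um^2
#' (pixel count times `pixel_size^2`). Defined on the first frame only, so
#' the value is invariant to everything that happens later in the movie.
#'
#' @param movie a [binary_movie()] with nonempty first frame (an empty first
#'   frame returns 0 with a warning).
#' @return Area in um^2.
#' @examples
#' f <- array(FALSE, c(20, 20, 1)); f[1:10, 1:10, 1] <- TRUE
#' territory_area(binary_movie(f, 0.5, 30))  # 100 px * 0.25 um^2
#' @export
territory_area <- function(movie) {
  stopifnot(inherits(movie, "binary_movie"))
  n <- sum(movie$frames[, , 1])
  if (n == 0L) {
    warning("empty first frame; territory area is 0")
    return(0)
  }
  n * movie$pixel_size^2
}

#' Per-frame surveillance table
#'
#' Long-format data.frame view of a [surveillance_index()] result, matching
#' the CSV the CLI emits: one row per frame pair plus a summary row.
#'
#' @param result a `surveillance_result`.
#' @return data.frame with columns `frame`, `pe`, `pr`, `index`; the summary
#'   row has `frame = NA` and `index = mean_index`.
#' @export
surveillance_table <- function(result) {
  stopifnot(inherits(result, "surveillance_result"))
  rbind(
    data.frame(frame = seq_along(result$index_per_frame) + 1L,
               pe = result$pe_counts, pr = result$pr_counts,
               index = result$index_per_frame),
    data.frame(frame = NA_integer_, pe = NA_integer_, pr = NA_integer_,
               index = result$mean_index))
}
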