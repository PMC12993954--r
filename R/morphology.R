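# Reconstruction-based morphometrics (SWC trees) and 2D cell-shape metrics.

#' Validate and construct a morphology tree
#'
#' A `morph_tree` wraps a validated SWC node table: columns `id`, `type`,
#' `x`, `y`, `z`, `radius`, `parent` (coordinates in um; exactly one root
#' with `parent = -1`, every other parent referencing an existing node, and
#' an acyclic parent graph).
#'
#' @param nodes data.frame with the seven SWC columns.
#' @return An object of class `morph_tree`.
#' @export
as_morph_tree <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("nodes must have columns ", paste(need, collapse = ", "))
  nodes <- nodes[, need]
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  if (any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("node coordinates must be finite")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L)
    stop("tree must have exactly one root (parent = -1); found ",
         length(roots))
  known <- nodes$parent %in% c(-1L, nodes$id)
  if (!all(known))
    stop("parent references missing id: ",
         nodes$parent[!known][1], " (line ", which(!known)[1], ")")
  # acyclicity: walk every parent chain; a chain longer than n nodes loops
  pidx <- match(nodes$parent, nodes$id)
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (!is.na(pidx[j])) {
      j <- pidx[j]; steps <- steps + 1L
      if (steps > n) stop("cycle detected involving node id ", nodes$id[i])
    }
  }
  structure(list(nodes = nodes, root = nodes$id[roots]),
            class = "morph_tree")
}

#' @export
print.morph_tree <- function(x, ...) {
  cat(sprintf("<morph_tree> %d nodes, root id %d, total length %.2f um\n",
              nrow(x$nodes), x$root, total_process_length(x)))
  invisible(x)
}

#' Read / write SWC reconstruction files
#'
#' Standard SWC dialect: whitespace-delimited lines of
#' `id type x y z radius parent`, `#` comments skipped, root parent `-1`.
#' Malformed files (wrong column count, duplicate ids, orphan parents,
#' cycles) raise an error naming the offending line or id.
#'
#' @param path file path.
#' @return `read_swc()` returns a `morph_tree`; `write_swc()` returns
#'   `path` invisibly.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop("no node lines in ", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("line ", which(keep)[bad[1]], " of ", path,
         " does not have 7 fields")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (any(!is.finite(m)))
    stop("non-numeric field in ", path)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  as_morph_tree(nodes)
}

#' @rdname read_swc
#' @param tree a `morph_tree`.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "morph_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by microdyn", con)
  write.table(tree$nodes, con, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# per-node index of parent row (NA for root) and edge lengths into each node
tree_edges <- function(tree) {
  nodes <- tree$nodes
  pidx <- match(nodes$parent, nodes$id)
  len <- sqrt((nodes$x - nodes$x[pidx])^2 +
              (nodes$y - nodes$y[pidx])^2 +
              (nodes$z - nodes$z[pidx])^2)
  list(pidx = pidx, len = len)
}

#' Total process length
#'
#' Sum over all non-root nodes of the Euclidean distance to the parent node,
#' in um.
#'
#' @param tree a `morph_tree`.
#' @return Length in um (0 for a soma-only tree).
#' @export
total_process_length <- function(tree) {
  stopifnot(inherits(tree, "morph_tree"))
  e <- tree_edges(tree)
  sum(e$len, na.rm = TRUE)
}

#' Number of branch points
#'
#' Non-soma nodes with at least two children. The soma is excluded by
#' default even when several primary processes leave it — primary-process
#' roots are not branchings of a process; set `include_soma = TRUE` for the
#' alternative convention.
#'
#' @param tree a `morph_tree`.
#' @param include_soma count the soma when it has >= 2 children?
#' @return Integer count.
#' @export
branch_points <- function(tree, include_soma = FALSE) {
  stopifnot(inherits(tree, "morph_tree"))
  nodes <- tree$nodes
  nch <- tabulate(match(nodes$parent, nodes$id), nbins = nrow(nodes))
  is_bp <- nch >= 2L
  if (!include_soma) is_bp[nodes$id == tree$root] <- FALSE
  sum(is_bp)
}

#' Sholl analysis of a reconstruction
#'
#' Counts, for spheres of increasing radius centred on the soma, the tree
#' edges crossing each sphere: an edge with endpoint distances `d_parent`
#' and `d_child` crosses radius `r` under the half-open rule
#' `min(d) < r <= max(d)` (an edge exactly touching a sphere at its outer
#' endpoint counts once; no double counting). Radii run from `radius_step`
#' in steps of `radius_step` up to one step beyond the maximum node
#' distance, so the curve always ends on a zero. The per-cell summary is the
#' trapezoidal area under the intersections-vs-radius curve (AUC).
#'
#' @param tree a `morph_tree`.
#' @param radius_step sphere spacing, um.
#' @return An object of class `sholl_curve`: `radii`, `intersections`,
#'   `auc`.
#' @export
sholl <- function(tree, radius_step = 1) {
  stopifnot(inherits(tree, "morph_tree"))
  if (radius_step <= 0) stop("'radius_step' must be > 0")
  nodes <- tree$nodes
  ridx <- which(nodes$id == tree$root)
  if (length(ridx) != 1L) stop("soma (root) missing")
  d <- sqrt((nodes$x - nodes$x[ridx])^2 + (nodes$y - nodes$y[ridx])^2 +
            (nodes$z - nodes$z[ridx])^2)
  e <- tree_edges(tree)
  nonroot <- which(!is.na(e$pidx))
  if (length(nonroot) == 0L)
    return(structure(list(radii = numeric(0), intersections = integer(0),
                          auc = 0), class = "sholl_curve"))
  dlo <- pmin(d[nonroot], d[e$pidx[nonroot]])
  dhi <- pmax(d[nonroot], d[e$pidx[nonroot]])
  radii <- radius_step * seq_len(floor(max(d) / radius_step) + 1L)
  inter <- vapply(radii, function(r) sum(dlo < r & r <= dhi), integer(1))
  structure(list(radii = radii, intersections = inter,
                 auc = trapz(radii, inter)),
            class = "sholl_curve")
}

#' @export
print.sholl_curve <- function(x, ...) {
  cat(sprintf("<sholl_curve> %d radii, max %d intersections, AUC %.2f\n",
              length(x$radii),
              if (length(x$intersections)) max(x$intersections) else 0L,
              x$auc))
  invisible(x)
}

#' Filopodia count from terminal tip lengths
#'
#' For each terminal (leaf) node, the tip length is the path length from the
#' leaf back along the tree to the nearest ancestor that is a branch point
#' or the soma (the sum of segment lengths, not the straight-line
#' distance). Tips with length in `[min_length, max_length)` um count as
#' filopodia — short dynamic branchlets below the main reconstruction
#' scale. Also reported per 10 um of total process length.
#'
#' @param tree a `morph_tree` with at least one terminal node.
#' @param min_length,max_length half-open tip-length window, um; defaults 1
#'   and 5 (the lower bound is the reconstruction floor).
#' @return A list with `count`, `per_10um` and `tip_lengths` (per leaf).
#' @export
filopodia_count <- function(tree, min_length = 1, max_length = 5) {
  stopifnot(inherits(tree, "morph_tree"))
  nodes <- tree$nodes
  n <- nrow(nodes)
  e <- tree_edges(tree)
  nch <- tabulate(e$pidx[!is.na(e$pidx)], nbins = n)
  leaves <- which(nch == 0L & nodes$id != tree$root)
  if (length(leaves) == 0L)
    return(list(count = 0L, per_10um = NA_real_, tip_lengths = numeric(0)))
  root_row <- which(nodes$id == tree$root)
  tip_lengths <- vapply(leaves, function(l) {
    s <- 0
    while (l != root_row) {
      s <- s + e$len[l]
      p <- e$pidx[l]
      if (p == root_row || nch[p] >= 2L) break
      l <- p
    }
    s
  }, numeric(1))
  count <- sum(tip_lengths >= min_length & tip_lengths < max_length)
  total <- total_process_length(tree)
  if (total == 0 && count > 0)
    stop("zero total process length with nonzero filopodia count")
  per10 <- if (total > 0) count * 10 / total else NA_real_
  list(count = count, per_10um = per10, tip_lengths = tip_lengths)
}

#' 2D cell-shape metrics from a mask and actin channels
#'
#' Area is the foreground pixel count times `pixel_size^2`. The perimeter is
#' estimated as the length of the 0.5-level marching-squares contour of the
#' mask after Gaussian regularization (sigma = 2 px): the raw staircase
#' contour of a digitized boundary systematically overestimates length, and
#' the regularized contour tracks the underlying smooth boundary (estimator
#' name recorded in the result because circularity is estimator-sensitive).
#' Circularity is `4 * pi * area / perimeter^2`; the F/G ratio is the mean
#' of `f_channel` over the mask divided by the mean of `g_channel` over the
#' mask.
#'
#' @param mask logical matrix, nonempty.
#' @param pixel_size um per pixel.
#' @param f_channel,g_channel optional co-registered intensity matrices
#'   (F-actin and G-actin); both or neither.
#' @param sigma Gaussian regularization SD for the contour, px.
#' @return An object of class `shape_metrics`: `area` (um^2), `perimeter`
#'   (um), `circularity`, `fg_ratio` (`NA` with a warning when the G-channel
#'   mean is 0 or channels are absent), `perimeter_estimator`.
#' @export
shape_metrics <- function(mask, pixel_size, f_channel = NULL,
                          g_channel = NULL, sigma = 2) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("mask is empty")
  area_px <- sum(mask)
  perim_px <- contour_perimeter(mask, sigma)
  area <- area_px * pixel_size^2
  perimeter <- perim_px * pixel_size
  fg_ratio <- NA_real_
  if (!is.null(f_channel) && !is.null(g_channel)) {
    gm <- mean(g_channel[mask])
    if (gm == 0) {
      warning("G-channel mean over the mask is 0; fg_ratio undefined")
    } else {
      fg_ratio <- mean(f_channel[mask]) / gm
    }
  }
  structure(
    list(area = area, perimeter = perimeter,
         circularity = 4 * pi * area / perimeter^2,
         fg_ratio = fg_ratio,
         perimeter_estimator = sprintf(
           "gaussian-regularized marching squares (sigma = %g px)", sigma)),
    class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf(
    "<shape_metrics> area %.2f um^2, perimeter %.2f um, circularity %.3f",
    x$area, x$perimeter, x$circularity))
  if (!is.na(x$fg_ratio)) cat(sprintf(", F/G %.3f", x$fg_ratio))
  cat("\n")
  invisible(x)
}

# contour length (px) of the 0.5 level of the Gaussian-smoothed mask
contour_perimeter <- function(mask, sigma = 2) {
  H <- nrow(mask); W <- ncol(mask)
  p <- as.integer(ceiling(3 * sigma)) + 1L
  z <- matrix(0, H + 2L * p, W + 2L * p)
  z[p + (1:H), p + (1:W)] <- mask
  zs <- if (sigma > 0) EBImage::gblur(z, sigma) else z
  cl <- contourLines(x = seq_len(nrow(zs)), y = seq_len(ncol(zs)),
                     z = zs, levels = 0.5)
  if (length(cl) == 0L) return(0)
  sum(vapply(cl, function(cc) {
    x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
}

#' Per-cell morphology metrics table
#'
#' Convenience wrapper computing all reconstruction metrics for one tree.
#'
#' @param tree a `morph_tree`.
#' @param radius_step Sholl sphere spacing, um.
#' @param cell id recorded in the output row.
#' @return One-row data.frame: `cell`, `total_length_um`, `branch_points`,
#'   `filopodia`, `filopodia_per_10um`, `sholl_auc`.
#' @export
morphology_metrics <- function(tree, radius_step = 1, cell = "cell") {
  fil <- filopodia_count(tree)
  data.frame(cell = cell,
             total_length_um = total_process_length(tree),
             branch_points = branch_points(tree),
             filopodia = fil$count,
             filopodia_per_10um = fil$per_10um,
             sholl_auc = sholl(tree, radius_step)$auc)
}
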