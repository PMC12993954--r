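# Independent brute-force oracles. These deliberately share no code with the
# package implementation: explicit loops and direct arithmetic only.

# changed-pixel count between two frames by explicit double loop
brute_change_count <- function(f1, f2) {
  n <- 0L
  for (i in seq_len(nrow(f1)))
    for (j in seq_len(ncol(f1)))
      if (f1[i, j] != f2[i, j]) n <- n + 1L
  n
}

# per-pixel polar classification: ring and sector for every pixel, NA
# outside max_radius; 0-based pixel coordinates, x = col, y = row
brute_polar_classify <- function(H, W, cx, cy, pixel_size, ring_width,
                                 n_sectors, max_radius) {
  ring <- sector <- matrix(NA_integer_, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      dx <- (j - 1) - cx
      dy <- (i - 1) - cy
      r <- sqrt(dx^2 + dy^2) * pixel_size
      if (r < max_radius) {
        ring[i, j] <- as.integer(floor(r / ring_width))
        a <- atan2(dy, dx)
        if (a < 0) a <- a + 2 * pi
        s <- floor(a / (2 * pi / n_sectors))
        if (s >= n_sectors) s <- n_sectors - 1
        sector[i, j] <- as.integer(s)
      }
    }
  }
  list(ring = ring, sector = sector)
}

# per-edge summation of a node table read straight from an SWC data.frame
brute_tree_length <- function(nodes) {
  total <- 0
  for (k in seq_len(nrow(nodes))) {
    p <- nodes$parent[k]
    if (p == -1) next
    pr <- nodes[nodes$id == p, ]
    total <- total + sqrt((nodes$x[k] - pr$x)^2 + (nodes$y[k] - pr$y)^2 +
                            (nodes$z[k] - pr$z)^2)
  }
  total
}

brute_branch_points <- function(nodes) {
  root <- nodes$id[nodes$parent == -1]
  n_bp <- 0L
  for (k in seq_len(nrow(nodes))) {
    id <- nodes$id[k]
    if (id == root) next
    if (sum(nodes$parent == id) >= 2L) n_bp <- n_bp + 1L
  }
  n_bp
}

# sphere-crossing count per radius by brute-force per-edge test
brute_sholl <- function(nodes, radii) {
  root <- nodes[nodes$parent == -1, ]
  dist_to_soma <- function(k)
    sqrt((nodes$x[k] - root$x)^2 + (nodes$y[k] - root$y)^2 +
           (nodes$z[k] - root$z)^2)
  counts <- integer(length(radii))
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    for (k in seq_len(nrow(nodes))) {
      p <- nodes$parent[k]
      if (p == -1) next
      dc <- dist_to_soma(k)
      dp <- dist_to_soma(which(nodes$id == p))
      if ((dp < r && r <= dc) || (dc < r && r <= dp))
        counts[ri] <- counts[ri] + 1L
    }
  }
  counts
}

# random boolean movie with drifting foreground probability
random_movie <- function(H, W, T_, p = 0.1, seed = 1,
                         pixel_size = 0.25, frame_interval = 30) {
  set.seed(seed)
  frames <- array(runif(H * W * T_) < p, c(H, W, T_))
  binary_movie(frames, pixel_size, frame_interval)
}

# random rigid motion (rotation + translation) applied to node coordinates
apply_rigid <- function(nodes, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  tr <- runif(3, -50, 50)
  xyz <- t(R %*% t(as.matrix(nodes[, c("x", "y", "z")]))) +
    matrix(tr, nrow(nodes), 3, byrow = TRUE)
  nodes$x <- xyz[, 1]; nodes$y <- xyz[, 2]; nodes$z <- xyz[, 3]
  nodes
}

# small ramified-cell config that fits fast test frames
small_motility_cfg <- function(...) {
  args <- list(image_shape = c(96L, 96L), n_frames = 6L,
               initial_length_range = c(4, 8))
  user <- list(...)
  args[names(user)] <- user
  do.call(motility_sim_config, args)
}
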