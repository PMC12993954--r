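# SWC morphometrics and 2D shape metrics.

straight_tree <- function(lengths, angle = 0) {
  # chain of segments along one ray from the soma
  n <- length(lengths)
  xs <- cumsum(lengths) * cos(angle)
  ys <- cumsum(lengths) * sin(angle)
  as_morph_tree(data.frame(
    id = 1:(n + 1), type = c(1L, rep(3L, n)),
    x = c(0, xs), y = c(0, ys), z = 0, radius = 1,
    parent = c(-1L, 1:n)))
}

test_that("SWC parsing validates structure and round-trips", {
  path <- tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 2 -1", "2 3 5 0 0 1 1"), path)
  tr <- read_swc(path)
  expect_equal(nrow(tr$nodes), 2)
  expect_equal(total_process_length(tr), 5)

  writeLines(c("1 1 0 0 0 2 -1", "2 3 5 0 0 1 9"), path)
  expect_error(read_swc(path), "missing id")
  writeLines(c("1 1 0 0 0 2 -1", "2 3 5 0 0 1"), path)
  expect_error(read_swc(path), "7 fields")
  writeLines(c("1 1 0 0 0 2 -1", "2 3 5 0 0 1 3", "3 3 6 0 0 1 2"), path)
  expect_error(read_swc(path), "cycle")
  writeLines(c("1 1 0 0 0 2 -1", "1 3 5 0 0 1 1"), path)
  expect_error(read_swc(path), "duplicate")

  sim <- simulate_tree(tree_sim_config(seed = 19))
  p2 <- tempfile(fileext = ".swc")
  write_swc(sim$tree, p2)
  back <- read_swc(p2)
  expect_equal(nrow(back$nodes), nrow(sim$tree$nodes))
  expect_identical(back$nodes$parent, sim$tree$nodes$parent)
  expect_equal(total_process_length(back), total_process_length(sim$tree))
})

test_that("total length and branch points on constructed trees", {
  soma <- as_morph_tree(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                                   radius = 2, parent = -1L))
  expect_equal(total_process_length(soma), 0)
  expect_identical(branch_points(soma), 0L)

  chain <- straight_tree(c(5, 15))
  expect_equal(total_process_length(chain), 20)
  expect_identical(branch_points(chain), 0L)

  # Y: one bifurcation
  y <- as_morph_tree(data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 10, 20, 10), y = c(0, 0, 0, 10), z = 0, radius = 1,
    parent = c(-1L, 1L, 2L, 2L)))
  expect_identical(branch_points(y), 1L)
  # soma with two primaries is not a branch point by default
  two <- as_morph_tree(data.frame(
    id = 1:3, type = c(1L, 3L, 3L), x = c(0, 10, -10), y = 0, z = 0,
    radius = 1, parent = c(-1L, 1L, 1L)))
  expect_identical(branch_points(two), 0L)
  expect_identical(branch_points(two, include_soma = TRUE), 1L)
})

test_that("Sholl on closed-form geometries and against the brute-force oracle", {
  straight <- straight_tree(c(10, 10))
  sc <- sholl(straight, 1)
  expect_equal(sc$radii, 1:21)
  expect_identical(sc$intersections, c(rep(1L, 20), 0L))
  expect_equal(sc$auc, 19.5)

  soma <- as_morph_tree(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                                   radius = 2, parent = -1L))
  empty <- sholl(soma, 1)
  expect_equal(length(empty$radii), 0)
  expect_equal(empty$auc, 0)

  # bifurcation at 10 um with a radial and an orthogonal 10 um daughter
  y <- as_morph_tree(data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 10, 20, 10), y = c(0, 0, 0, 10), z = 0, radius = 1,
    parent = c(-1L, 1L, 2L, 2L)))
  sy <- sholl(y, 1)
  expect_identical(sy$intersections[1:10], rep(1L, 10))    # r <= 10
  expect_identical(sy$intersections[11:14], rep(2L, 4))    # 10 < r <= sqrt(200)
  expect_identical(sy$intersections[15:20], rep(1L, 6))
  expect_identical(sy$intersections, brute_sholl(y$nodes, sy$radii))

  for (seed in c(3, 21)) {
    sim <- simulate_tree(tree_sim_config(seed = seed))
    sc <- sholl(sim$tree, 1)
    expect_identical(sc$intersections, brute_sholl(sim$tree$nodes, sc$radii))
    expect_lte(sc$auc, max(sc$intersections) * max(sc$radii))
  }
})

test_that("filopodia rule: half-open [1, 5) window on tip path lengths", {
  # terminal segments 0.5, 3, 4.9, 6 um off one branch point
  bp <- c(10, 0)
  mk <- function(i, len, ang) {
    c(id = i, type = 3, x = bp[1] + len * cos(ang),
      y = bp[2] + len * sin(ang), z = 0, radius = 0.5, parent = 2)
  }
  nodes <- rbind(
    data.frame(id = 1, type = 1, x = 0, y = 0, z = 0, radius = 2,
               parent = -1),
    data.frame(id = 2, type = 3, x = 10, y = 0, z = 0, radius = 1,
               parent = 1),
    as.data.frame(rbind(mk(3, 0.5, 0.3), mk(4, 3, 1.2), mk(5, 4.9, 2.0),
                        mk(6, 6, -1.1))))
  tr <- as_morph_tree(nodes)
  fil <- filopodia_count(tr)
  expect_identical(fil$count, 2L)
  expect_equal(sort(fil$tip_lengths), sort(c(0.5, 3, 4.9, 6)),
               tolerance = 1e-9)
  # per-10-um normalization
  expect_equal(fil$per_10um, 2 * 10 / total_process_length(tr))
  # boundary arithmetic: count 4 over 200 um -> 0.2 per 10 um
  expect_equal(4 * 10 / 200, 0.2)

  # tip length is path length to the nearest branch point, not to the leaf's
  # direct parent: a 2-segment terminal run of 1.5 + 1.5 um measures 3 um
  run <- as_morph_tree(data.frame(
    id = 1:5, type = c(1, 3, 3, 3, 3),
    x = c(0, 10, 10, 11.5, 13), y = c(0, 0, 10, 10, 10), z = 0,
    radius = 1, parent = c(-1, 1, 2, 3, 4)))
  # node 2 is not a branch point (single child chain): whole run from soma
  expect_equal(sort(filopodia_count(run)$tip_lengths), 10 + 10 + 1.5 + 1.5)
})

test_that("metrics are invariant under random rigid motions", {
  for (seed in c(5, 10)) {
    sim <- simulate_tree(tree_sim_config(n_filopodia = 3L, seed = seed))
    ref_len <- total_process_length(sim$tree)
    ref_bp <- branch_points(sim$tree)
    ref_sholl <- sholl(sim$tree, 1)
    ref_fil <- filopodia_count(sim$tree)$count
    for (k in 1:3) {
      moved <- as_morph_tree(apply_rigid(sim$tree$nodes, seed = 100 * seed + k))
      expect_equal(total_process_length(moved), ref_len, tolerance = 1e-9)
      expect_identical(branch_points(moved), ref_bp)
      ms <- sholl(moved, 1)
      expect_identical(ms$intersections, ref_sholl$intersections)
      expect_equal(ms$auc, ref_sholl$auc, tolerance = 1e-9)
      expect_identical(filopodia_count(moved)$count, ref_fil)
    }
  }
})

test_that("filopodia count never exceeds leaf count", {
  for (seed in 1:5) {
    sim <- simulate_tree(tree_sim_config(n_filopodia = 6L, seed = seed))
    nodes <- sim$tree$nodes
    n_leaves <- sum(!(nodes$id %in% nodes$parent))
    expect_lte(filopodia_count(sim$tree)$count, n_leaves)
  }
})

test_that("shape metrics: disc and square circularity, F/G ratio", {
  n <- 121
  ix <- matrix(rep(1:n, n), n); iy <- t(ix)
  disc <- (ix - 61)^2 + (iy - 61)^2 <= 50^2
  sm <- shape_metrics(disc, pixel_size = 0.2)
  expect_equal(sm$area, sum(disc) * 0.04)
  expect_gte(sm$circularity, 0.95)
  expect_lte(sm$circularity, 1.05)

  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  smq <- shape_metrics(sq, pixel_size = 0.2)
  expect_equal(smq$circularity, pi / 4, tolerance = 0.05)

  # circularity strictly decreases as an ellipse elongates
  circ_at <- function(b) {
    e <- (ix - 61)^2 / 50^2 + (iy - 61)^2 / b^2 <= 1
    shape_metrics(e, 0.2)$circularity
  }
  cs <- vapply(c(50, 35, 25, 15), circ_at, numeric(1))
  expect_true(all(diff(cs) < 0))

  f <- matrix(4, n, n); g <- matrix(2, n, n)
  smf <- shape_metrics(disc, 0.2, f_channel = f, g_channel = g)
  expect_equal(smf$fg_ratio, 2)
  expect_warning(
    smz <- shape_metrics(disc, 0.2, f_channel = f,
                         g_channel = matrix(0, n, n)),
    "undefined")
  expect_true(is.na(smz$fg_ratio))
})

test_that("morphology_metrics aggregates one row per cell", {
  sim <- simulate_tree(tree_sim_config(seed = 2))
  row <- morphology_metrics(sim$tree, cell = "c1")
  expect_equal(row$total_length_um, sim$ground_truth$total_length)
  expect_equal(row$branch_points, sim$ground_truth$branch_points)
  expect_equal(row$filopodia, sim$ground_truth$filopodia)
  expect_equal(row$sholl_auc, sholl(sim$tree, 1)$auc)
})
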