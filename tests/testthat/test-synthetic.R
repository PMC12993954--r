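# Synthetic-data generators: determinism, constructive ground truth,
# self-consistency with brute-force recomputation.

test_that("generators are deterministic: identical config + seed, identical output", {
  a <- simulate_surveillance_movie(small_motility_cfg(seed = 9))
  b <- simulate_surveillance_movie(small_motility_cfg(seed = 9))
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$ground_truth, b$ground_truth)

  cfg <- chemotaxis_sim_config(image_shape = c(240L, 240L), n_frames = 4L,
                               initial_front_radius = 20, seed = 5)
  expect_identical(simulate_chemotaxis_movie(cfg)$movie$frames,
                   simulate_chemotaxis_movie(cfg)$movie$frames)

  tcfg <- tree_sim_config(seed = 4)
  expect_identical(simulate_tree(tcfg)$tree$nodes,
                   simulate_tree(tcfg)$tree$nodes)

  hcfg <- hier_sim_config(seed = 12)
  expect_identical(simulate_hierarchical_table(hcfg),
                   simulate_hierarchical_table(hcfg))
})

test_that("motility_scale = 0 freezes the movie and zeroes the ground truth", {
  sim <- simulate_surveillance_movie(small_motility_cfg(motility_scale = 0,
                                                        seed = 2))
  expect_true(all(sim$ground_truth$change_counts == 0L))
  for (t in 2:dim(sim$movie$frames)[3])
    expect_identical(sim$movie$frames[, , t], sim$movie$frames[, , 1])
})

test_that("ground-truth change counts equal brute-force XOR pixel counts", {
  for (seed in c(1, 7, 23)) {
    sim <- simulate_surveillance_movie(small_motility_cfg(seed = seed))
    f <- sim$movie$frames
    for (t in 2:dim(f)[3])
      expect_identical(sim$ground_truth$change_counts[t - 1],
                       brute_change_count(f[, , t - 1], f[, , t]))
  }
})

test_that("mean change count increases with motility_scale over a seed ensemble", {
  seeds <- 1:20
  mean_change <- function(scale) {
    mean(vapply(seeds, function(s)
      mean(simulate_surveillance_movie(
        small_motility_cfg(motility_scale = scale, seed = s)
      )$ground_truth$change_counts), numeric(1)))
  }
  lo <- mean_change(0.4)
  hi <- mean_change(1.0)
  expect_lt(lo, hi)
})

test_that("too-small images are rejected with an informative message", {
  expect_error(
    simulate_surveillance_movie(
      motility_sim_config(image_shape = c(32L, 32L),
                          initial_length_range = c(10, 22))),
    "too small")
})

test_that("chemotaxis ground truth follows the programmed front arithmetic", {
  base <- list(image_shape = c(400L, 400L), n_frames = 6L, seed = 3)
  still <- simulate_chemotaxis_movie(do.call(chemotaxis_sim_config,
    c(base, list(convergence_speed = 0))))
  expect_identical(diff(still$ground_truth$front_radius), rep(0, 5))

  mv <- simulate_chemotaxis_movie(do.call(chemotaxis_sim_config,
    c(base, list(convergence_speed = 2, frame_interval = 30))))
  expect_equal(diff(mv$ground_truth$front_radius), rep(-1, 5))

  # floored at the lesion radius
  fl <- simulate_chemotaxis_movie(do.call(chemotaxis_sim_config,
    c(base, list(convergence_speed = 40, lesion_diameter = 15,
                 initial_front_radius = 20))))
  expect_equal(min(fl$ground_truth$front_radius), 7.5)

  expect_error(chemotaxis_sim_config(initial_front_radius = 5,
                                     lesion_diameter = 15),
               "exceed the lesion radius")
  expect_error(
    simulate_chemotaxis_movie(
      chemotaxis_sim_config(image_shape = c(100L, 100L),
                            initial_front_radius = 40)),
    "outside the image")
})

test_that("tree generator: constructed cases give exact ground truth", {
  one <- simulate_tree(tree_sim_config(n_primary = 1L,
                                       branch_probability = 0,
                                       segment_length_range = c(20, 20),
                                       max_depth = 1L, n_filopodia = 0L,
                                       seed = 1))
  expect_equal(one$ground_truth$total_length, 20)
  expect_identical(one$ground_truth$branch_points, 0L)
  expect_identical(one$ground_truth$filopodia, 0L)
  expect_equal(total_process_length(one$tree), 20)

  filo <- simulate_tree(tree_sim_config(n_primary = 2L,
                                        branch_probability = 0.5,
                                        n_filopodia = 7L, seed = 8))
  expect_identical(filo$ground_truth$filopodia, 7L)
  expect_identical(filopodia_count(filo$tree)$count, 7L)
})

test_that("tree ground truth matches independent per-edge recomputation", {
  for (seed in c(2, 13, 31, 44)) {
    sim <- simulate_tree(tree_sim_config(n_primary = 3L,
                                         branch_probability = 0.4,
                                         n_filopodia = 4L, seed = seed))
    nodes <- sim$tree$nodes
    expect_equal(sim$ground_truth$total_length, brute_tree_length(nodes),
                 tolerance = 1e-12)
    expect_identical(sim$ground_truth$branch_points,
                     brute_branch_points(nodes))
    expect_identical(total_process_length(sim$tree),
                     sim$ground_truth$total_length)
    expect_identical(branch_points(sim$tree), sim$ground_truth$branch_points)
    expect_identical(filopodia_count(sim$tree)$count,
                     sim$ground_truth$filopodia)
  }
})

test_that("organelle fixtures carry exact constructive ground truth", {
  none <- simulate_organelle_volume(cell_axes = c(2, 3, 3),
                                    voxel_size = c(0.5, 0.2, 0.2))
  expect_equal(none$ground_truth$volume_fraction_pct, 0)
  expect_identical(none$ground_truth$lysosome_count, 0L)

  mix <- simulate_organelle_volume(
    cell_axes = c(3, 5, 5),
    lysosome_specs = list(list(center = c(0, -2.5, 0), radius = 1),
                          list(center = c(0, 2.5, 1), radius = 0.8),
                          list(center = c(1, 0, -2.5), radius = 0.7)),
    puncta_specs = list(
      list(center = c(0, -2.5, 0), inside_lysosome = TRUE),
      list(center = c(0, 2.5, 1), inside_lysosome = TRUE),
      list(center = c(1, 0, -2.5), inside_lysosome = TRUE),
      list(center = c(0, 0, 3.5), inside_lysosome = FALSE),
      list(center = c(-1, 3.5, -2), inside_lysosome = FALSE)),
    voxel_size = c(0.5, 0.2, 0.2))
  expect_identical(mix$ground_truth$puncta_in_lysosomes, 3L)
  expect_identical(mix$ground_truth$lysosome_count, 3L)
  expect_equal(mix$ground_truth$volume_fraction_pct,
               100 * sum(mix$ground_truth$lysosome_voxels) /
                 mix$ground_truth$cell_voxels)
})

test_that("hierarchical table: zero SDs give exact group means, balanced design", {
  cfg <- hier_sim_config(n_animals_per_group = 3L, n_slices_per_animal = 2L,
                         n_cells_per_slice = 4L, beta0 = 1.5, beta1 = -2,
                         sd_animal = 0, sd_slice = 0, sd_cell = 0, seed = 6)
  tab <- simulate_hierarchical_table(cfg)
  expect_equal(nrow(tab), 2 * 3 * 2 * 4)
  expect_true(all(tab$value[tab$group == "control"] == 1.5))
  expect_true(all(tab$value[tab$group == "treated"] == -0.5))
  expect_equal(length(unique(tab$animal)), 6L)
})

test_that("hierarchical variance components are recovered at large n", {
  cfg <- hier_sim_config(n_animals_per_group = 30L, n_slices_per_animal = 3L,
                         n_cells_per_slice = 6L, beta1 = 0,
                         sd_animal = 1, sd_slice = 0.5, sd_cell = 1,
                         seed = 77)
  tab <- simulate_hierarchical_table(cfg)
  fit <- fit_lmem(tab, slice_component = TRUE)
  expect_equal(fit$var_animal, 1, tolerance = 0.4)
  expect_equal(fit$var_slice, 0.25, tolerance = 0.4)
  expect_equal(fit$var_residual, 1, tolerance = 0.15)
})

test_that("YAML configs round-trip into simulator configs", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("type: motility", "image_shape: [96, 96]", "n_frames: 6",
               "motility_scale: 0.4", "initial_length_range: [4, 8]",
               "seed: 3"), path)
  cfg <- sim_config_from_yaml(path)
  expect_s3_class(cfg, "motility_sim_config")
  expect_equal(cfg$motility_scale, 0.4)
  cfg2 <- sim_config_from_yaml(path, seed = 99L)
  expect_equal(cfg2$seed, 99L)
  sim <- simulate_surveillance_movie(cfg)
  expect_equal(dim(sim$movie$frames), c(96L, 96L, 6L))
})

test_that("packaged example configs load and run", {
  dir <- system.file("extdata", "configs", package = "microdyn")
  files <- list.files(dir, full.names = TRUE)
  expect_gte(length(files), 3L)
  for (f in files) expect_no_error(sim_config_from_yaml(f))
})
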