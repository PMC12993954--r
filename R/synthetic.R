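# Synthetic-data generators. Every generator returns the artifact plus a
# ground-truth record computed constructively during generation, so that
# each downstream metric can be verified against known truth.

#' Configuration for the surveillance-movie simulator
#'
#' Defaults emulate the acquisition regime of the study data the pipeline is
#' designed for: 512 x 512 px fields imaged every 30 s for 10 min
#' (21 frames). `motility_scale` multiplies both tip rates and stands in for
#' a treatment or genotype effect on process motility.
#'
#' @param image_shape integer `(H, W)` in pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames.
#' @param pixel_size micrometres per pixel.
#' @param n_primary_processes number of processes radiating from the soma.
#' @param tip_extension_rate mean per-frame tip extension, um/frame.
#' @param tip_retraction_rate mean per-frame tip retraction, um/frame.
#' @param motility_scale dimensionless multiplier on both rates (>= 0);
#'   0 freezes the cell.
#' @param process_thickness rasterized process thickness, px.
#' @param soma_radius soma radius, um.
#' @param initial_length_range range (um) for initial process lengths.
#' @param seed integer RNG seed; identical config + seed gives a
#'   bit-identical movie.
#' @return A `motility_sim_config` list.
#' @export
motility_sim_config <- function(image_shape = c(512L, 512L),
                                n_frames = 21L,
                                frame_interval = 30,
                                pixel_size = 0.25,
                                n_primary_processes = 6L,
                                tip_extension_rate = 0.8,
                                tip_retraction_rate = 0.8,
                                motility_scale = 1,
                                process_thickness = 3,
                                soma_radius = 3,
                                initial_length_range = c(10, 22),
                                seed = 1L) {
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  if (tip_extension_rate < 0 || tip_retraction_rate < 0)
    stop("tip rates must be >= 0")
  if (motility_scale < 0) stop("'motility_scale' must be >= 0")
  structure(as.list(environment()), class = "motility_sim_config")
}

#' Simulate a binarized surveillance movie of a ramified cell
#'
#' Generates a boolean movie of a soma-centred star of processes whose tips
#' lengthen and shorten stochastically each frame. Per-frame length
#' increments are drawn from a symmetric two-sided exponential mixture with
#' means `tip_extension_rate` and `tip_retraction_rate`, both multiplied by
#' `motility_scale`; lengths are clipped to stay inside the image. Processes
#' are rasterized as all pixels within `process_thickness / 2` of the
#' centreline segment (no anti-aliasing; the substrate is boolean).
#'
#' The ground truth records, for each consecutive frame pair, the exact
#' number of pixels that changed state — the quantity the surveillance index
#' measures.
#'
#' @param cfg a [motility_sim_config()].
#' @return A list with `movie` (a [binary_movie()]) and `ground_truth`
#'   (list with `change_counts`, length `n_frames - 1`).
#' @examples
#' sim <- simulate_surveillance_movie(
#'   motility_sim_config(image_shape = c(96, 96), n_frames = 5, seed = 7))
#' sim$ground_truth$change_counts
#' @export
simulate_surveillance_movie <- function(cfg) {
  stopifnot(inherits(cfg, "motility_sim_config"))
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  halfw <- cfg$process_thickness / 2
  # maximum tip radius (um) that keeps the rasterized tip inside the image
  max_r_um <- (min(cx, cy) - halfw - 1) * cfg$pixel_size
  if (cfg$soma_radius + max(cfg$initial_length_range) > max_r_um)
    stop("image too small to contain soma plus initial processes; ",
         "enlarge 'image_shape' or shorten 'initial_length_range'")
  with_seed(cfg$seed, {
    n <- cfg$n_primary_processes
    angles <- runif(n, 0, 2 * pi)
    len <- runif(n, cfg$initial_length_range[1], cfg$initial_length_range[2])
    frames <- array(FALSE, c(H, W, cfg$n_frames))
    soma_px <- cfg$soma_radius / cfg$pixel_size
    rasterize <- function(len) {
      m <- matrix(FALSE, H, W)
      m <- raster_disc(m, cx, cy, soma_px)
      r_px <- (cfg$soma_radius + len) / cfg$pixel_size
      for (i in seq_len(n))
        m <- raster_segment(m, cx, cy,
                            cx + cos(angles[i]) * r_px[i],
                            cy + sin(angles[i]) * r_px[i], halfw)
      m
    }
    frames[, , 1] <- rasterize(len)
    change_counts <- integer(cfg$n_frames - 1L)
    for (t in 2:cfg$n_frames) {
      inc <- cfg$motility_scale *
        (rexp(n, rate = 1 / max(cfg$tip_extension_rate, 1e-12)) -
         rexp(n, rate = 1 / max(cfg$tip_retraction_rate, 1e-12)))
      if (cfg$motility_scale == 0 ||
          (cfg$tip_extension_rate == 0 && cfg$tip_retraction_rate == 0))
        inc <- rep(0, n)
      len <- pmin(pmax(len + inc, 0), max_r_um - cfg$soma_radius)
      frames[, , t] <- rasterize(len)
      change_counts[t - 1L] <- sum(frames[, , t] != frames[, , t - 1L])
    }
    list(movie = binary_movie(frames, cfg$pixel_size, cfg$frame_interval),
         ground_truth = list(change_counts = change_counts))
  })
}

#' Configuration for the chemotaxis-movie simulator
#'
#' Defaults emulate recordings of processes converging on a circular focal
#' lesion of 15 um diameter. The programmed front radius at frame `t` is
#' `initial_front_radius - convergence_speed * (t - 1) * frame_interval / 60`,
#' floored at the lesion radius.
#'
#' @param image_shape integer `(H, W)` in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames.
#' @param pixel_size micrometres per pixel.
#' @param lesion_center `(x, y)` 0-based pixel coordinates; default image
#'   centre.
#' @param lesion_diameter lesion diameter, um.
#' @param n_processes number of converging processes.
#' @param convergence_speed inward front speed, um/min (>= 0).
#' @param initial_front_radius starting front radius, um; must exceed the
#'   lesion radius and lie inside the image.
#' @param process_length radial extent of each rasterized process, um.
#' @param process_thickness process thickness, px.
#' @param angle_jitter fraction of a sector width by which process angles
#'   are jittered around an even angular spread.
#' @param seed integer RNG seed.
#' @return A `chemotaxis_sim_config` list.
#' @export
chemotaxis_sim_config <- function(image_shape = c(512L, 512L),
                                  n_frames = 21L,
                                  frame_interval = 30,
                                  pixel_size = 0.25,
                                  lesion_center = NULL,
                                  lesion_diameter = 15,
                                  n_processes = 48L,
                                  convergence_speed = 2,
                                  initial_front_radius = 40,
                                  process_length = 12,
                                  process_thickness = 5,
                                  angle_jitter = 0.5,
                                  seed = 1L) {
  if (lesion_diameter <= 0) stop("'lesion_diameter' must be > 0")
  if (convergence_speed < 0) stop("'convergence_speed' must be >= 0")
  if (initial_front_radius <= lesion_diameter / 2)
    stop("'initial_front_radius' must exceed the lesion radius")
  if (is.null(lesion_center))
    lesion_center <- c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2)
  structure(as.list(environment()), class = "chemotaxis_sim_config")
}

#' Simulate a binarized movie of processes converging on a lesion
#'
#' Processes are radial segments advancing toward `lesion_center` at
#' `convergence_speed`; the programmed front radius per frame is recorded as
#' ground truth (floored at the lesion radius).
#'
#' @param cfg a [chemotaxis_sim_config()].
#' @return A list with `movie` (a [binary_movie()]) and `ground_truth`
#'   (list with `front_radius`, um per frame, and `lesion_center`).
#' @export
simulate_chemotaxis_movie <- function(cfg) {
  stopifnot(inherits(cfg, "chemotaxis_sim_config"))
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  cx <- cfg$lesion_center[1]; cy <- cfg$lesion_center[2]
  edge_um <- min(cx, W - 1 - cx, cy, H - 1 - cy) * cfg$pixel_size
  if (cfg$initial_front_radius >= edge_um)
    stop("front radius would start outside the image; ",
         "reduce 'initial_front_radius' or enlarge 'image_shape'")
  lesion_r <- cfg$lesion_diameter / 2
  with_seed(cfg$seed, {
    n <- cfg$n_processes
    base <- (seq_len(n) - 0.5) * 2 * pi / n
    angles <- base + runif(n, -1, 1) * cfg$angle_jitter * pi / n
    front <- pmax(lesion_r,
                  cfg$initial_front_radius -
                    cfg$convergence_speed *
                      (seq_len(cfg$n_frames) - 1) * cfg$frame_interval / 60)
    frames <- array(FALSE, c(H, W, cfg$n_frames))
    halfw <- cfg$process_thickness / 2
    for (t in seq_len(cfg$n_frames)) {
      m <- matrix(FALSE, H, W)
      r0 <- front[t] / cfg$pixel_size
      r1 <- (front[t] + cfg$process_length) / cfg$pixel_size
      for (i in seq_len(n))
        m <- raster_segment(m,
                            cx + cos(angles[i]) * r0, cy + sin(angles[i]) * r0,
                            cx + cos(angles[i]) * r1, cy + sin(angles[i]) * r1,
                            halfw)
      frames[, , t] <- m
    }
    list(movie = binary_movie(frames, cfg$pixel_size, cfg$frame_interval),
         ground_truth = list(front_radius = front,
                             lesion_center = cfg$lesion_center))
  })
}

#' Configuration for the tree simulator
#'
#' Generates rooted SWC trees with controlled branch counts, total length and
#' filopodia. Backbone segment lengths default to 6-15 um — above the 5 um
#' filopodia upper bound — so that every programmed filopodium, and nothing
#' else, falls in the 1-5 um tip range.
#'
#' @param n_primary number of primary processes leaving the soma.
#' @param branch_probability per-segment probability of bifurcating.
#' @param segment_length_range range (um) of backbone segment lengths.
#' @param max_depth maximum number of segments along any backbone path.
#' @param n_filopodia number of short terminal branchlets to attach.
#' @param filopodia_length_range length range for filopodia; must be a
#'   subset of `[1, 5)` um.
#' @param seed integer RNG seed.
#' @return A `tree_sim_config` list.
#' @export
tree_sim_config <- function(n_primary = 4L,
                            branch_probability = 0.3,
                            segment_length_range = c(6, 15),
                            max_depth = 4L,
                            n_filopodia = 5L,
                            filopodia_length_range = c(1, 4.5),
                            seed = 1L) {
  if (any(segment_length_range <= 0)) stop("segment lengths must be > 0")
  if (filopodia_length_range[1] < 1 || filopodia_length_range[2] >= 5 ||
      filopodia_length_range[1] > filopodia_length_range[2])
    stop("'filopodia_length_range' must be a subset of [1, 5) um")
  if (min(segment_length_range) < 5 && n_filopodia > 0)
    warning("backbone segments shorter than 5 um may themselves count as ",
            "filopodia; ground truth is computed from the generated tree")
  structure(as.list(environment()), class = "tree_sim_config")
}

# unit vector with Gaussian angular jitter around `dir`
jitter_dir <- function(dir, sd = 0.4) {
  v <- dir + rnorm(3, 0, sd)
  n <- sqrt(sum(v^2))
  if (n < 1e-9) dir else v / n
}

#' Simulate an SWC tree with known morphometric ground truth
#'
#' Builds a rooted tree: `n_primary` processes leave the soma in random
#' directions; each segment bifurcates with `branch_probability` (up to
#' `max_depth` segments deep), then `n_filopodia` short terminal branchlets
#' are attached at randomly chosen internal nodes. Ground truth (total
#' length, branch points, filopodia count) is computed constructively from
#' the generated structure.
#'
#' @param cfg a [tree_sim_config()].
#' @return A list with `tree` (a `morph_tree`, see [read_swc()]) and
#'   `ground_truth` (list with `total_length`, `branch_points`, `filopodia`).
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "tree_sim_config"))
  with_seed(cfg$seed, {
    # node store; id 1 = soma at origin
    nodes <- list(list(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                       radius = 2, parent = -1L))
    seglen <- c(NA_real_)          # length of segment into node i
    nid <- 1L
    add_node <- function(parent, dir, len, type = 3L, radius = 0.5) {
      p <- nodes[[parent]]
      nid <<- nid + 1L
      nodes[[nid]] <<- list(id = nid, type = type,
                            x = p$x + dir[1] * len,
                            y = p$y + dir[2] * len,
                            z = p$z + dir[3] * len,
                            radius = radius, parent = parent)
      seglen[nid] <<- len
      nid
    }
    grow <- function(parent, dir, depth) {
      if (depth > cfg$max_depth) return(invisible())
      len <- runif(1, cfg$segment_length_range[1], cfg$segment_length_range[2])
      node <- add_node(parent, dir, len)
      if (depth < cfg$max_depth) {
        if (runif(1) < cfg$branch_probability) {
          grow(node, jitter_dir(dir, 0.6), depth + 1L)
          grow(node, jitter_dir(dir, 0.6), depth + 1L)
        } else if (runif(1) < 0.8) {
          grow(node, jitter_dir(dir, 0.25), depth + 1L)
        }
      }
      invisible()
    }
    for (i in seq_len(cfg$n_primary)) {
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
      grow(1L, v, 1L)
    }
    # attach filopodia at internal nodes (nodes that already have a child),
    # or at the soma, so attachment never extends an existing terminal run
    n_children <- tabulate(vapply(nodes[-1], `[[`, 1L, "parent"), nbins = nid)
    eligible <- which(n_children >= 1L)
    if (cfg$n_filopodia > 0L) {
      if (length(eligible) == 0L) eligible <- 1L
      at <- sample(rep(eligible, length.out = max(cfg$n_filopodia,
                                                  length(eligible))),
                   cfg$n_filopodia, replace = TRUE)
      for (p in at) {
        len <- runif(1, cfg$filopodia_length_range[1],
                     cfg$filopodia_length_range[2])
        add_node(p, jitter_dir(c(1, 0, 0), 2), len, type = 3L, radius = 0.2)
      }
    }
    df <- do.call(rbind, lapply(nodes, function(nd)
      data.frame(id = nd$id, type = nd$type, x = nd$x, y = nd$y, z = nd$z,
                 radius = nd$radius, parent = nd$parent)))
    tree <- as_morph_tree(df)
    # constructive ground truth from the stored segment lengths / topology
    parent <- df$parent
    n_children <- tabulate(parent[parent > 0], nbins = nid)
    total_length <- sum(seglen[-1])
    bp <- sum(n_children[-1] >= 2L)
    leaves <- which(n_children == 0L)
    tip_len <- vapply(leaves, function(l) {
      s <- 0
      while (l != 1L && n_children[l] < 2L) {
        s <- s + seglen[l]
        l <- parent[l]
        if (l == 1L || n_children[l] >= 2L) break
      }
      s
    }, numeric(1))
    filo <- sum(tip_len >= 1 & tip_len < 5)
    list(tree = tree,
         ground_truth = list(total_length = total_length,
                             branch_points = bp,
                             filopodia = filo,
                             n_nodes = nid))
  })
}

#' Simulate co-registered organelle volumes with ground truth
#'
#' Builds an ellipsoidal cell mask, spherical lysosome regions clipped to the
#' cell, and puncta as single-voxel seeds dilated once (6-neighbourhood).
#' Lysosome spheres must be pairwise disjoint so that per-sphere voxel
#' volumes are exact ground truth for connected-component analysis.
#'
#' @param cell_axes semi-axes of the cell ellipsoid `(z, y, x)` in um.
#' @param lysosome_specs list of `list(center = c(z, y, x) um, radius = um)`;
#'   centres are relative to the cell centre.
#' @param puncta_specs list of `list(center = c(z, y, x) um,
#'   inside_lysosome = logical)`.
#' @param voxel_size `(z, y, x)` um per voxel.
#' @param margin_um empty margin around the cell, um.
#' @return A list with `volumes` (an [organelle_volumes()]) and
#'   `ground_truth` (per-lysosome voxel counts and volumes, counts, and the
#'   number of puncta flagged inside lysosomes).
#' @export
simulate_organelle_volume <- function(cell_axes = c(4, 6, 6),
                                      lysosome_specs = list(),
                                      puncta_specs = list(),
                                      voxel_size = c(0.5, 0.1, 0.1),
                                      margin_um = 1) {
  stopifnot(length(cell_axes) == 3L, all(cell_axes > 0))
  dims <- as.integer(ceiling(2 * (cell_axes + margin_um) / voxel_size)) + 1L
  # voxel-centre physical coordinates relative to the grid centre
  ax <- lapply(1:3, function(i)
    (seq_len(dims[i]) - (dims[i] + 1) / 2) * voxel_size[i])
  cz <- array(ax[[1]], dims)
  cyy <- aperm(array(ax[[2]], dims[c(2, 1, 3)]), c(2, 1, 3))
  cxx <- aperm(array(ax[[3]], dims[c(3, 1, 2)]), c(2, 3, 1))
  cell <- (cz / cell_axes[1])^2 + (cyy / cell_axes[2])^2 +
    (cxx / cell_axes[3])^2 <= 1
  if (!any(cell)) stop("cell ellipsoid contains no voxels at this sampling")
  lyso <- array(FALSE, dims)
  lyso_voxels <- integer(length(lysosome_specs))
  if (length(lysosome_specs) >= 2L) {
    for (i in seq_along(lysosome_specs))
      for (j in seq_len(i - 1L)) {
        d <- sqrt(sum((lysosome_specs[[i]]$center -
                       lysosome_specs[[j]]$center)^2))
        if (d <= lysosome_specs[[i]]$radius + lysosome_specs[[j]]$radius +
            max(voxel_size) * 2)
          warning("lysosome spheres ", j, " and ", i,
                  " may touch; per-sphere ground truth can be inexact")
      }
  }
  for (i in seq_along(lysosome_specs)) {
    s <- lysosome_specs[[i]]
    m <- ((cz - s$center[1])^2 + (cyy - s$center[2])^2 +
          (cxx - s$center[3])^2) <= s$radius^2
    m <- m & cell
    lyso_voxels[i] <- sum(m)
    lyso <- lyso | m
  }
  puncta <- array(FALSE, dims)
  nearest_voxel <- function(center) {
    vapply(1:3, function(i) which.min(abs(ax[[i]] - center[i])), integer(1))
  }
  for (s in puncta_specs) {
    v <- nearest_voxel(s$center)
    # 1-voxel seed dilated once with the 6-neighbourhood cross
    for (off in list(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      w <- v + off
      if (all(w >= 1L) && all(w <= dims))
        puncta[w[1], w[2], w[3]] <- TRUE
    }
  }
  vol <- organelle_volumes(cell, lyso, puncta, voxel_size)
  voxel_um3 <- prod(voxel_size)
  inside <- if (length(puncta_specs))
    sum(vapply(puncta_specs, function(s) isTRUE(s$inside_lysosome),
               logical(1))) else 0L
  list(volumes = vol,
       ground_truth = list(
         lysosome_voxels = lyso_voxels,
         lysosome_volumes_um3 = lyso_voxels * voxel_um3,
         lysosome_count = sum(lyso_voxels > 0L),
         cell_voxels = sum(cell),
         volume_fraction_pct = 100 * sum(lyso_voxels) / sum(cell),
         puncta_in_lysosomes = inside))
}

#' Configuration for the hierarchical-table simulator
#'
#' Emulates cell-level measurements nested as cells within slices within
#' animals, two groups (control vs treated), with a group fixed effect and
#' independent zero-mean normal random components at each level:
#' `y = beta0 + beta1 * group + a_animal + s_slice + e_cell`.
#'
#' @param n_animals_per_group,n_slices_per_animal,n_cells_per_slice design.
#' @param beta0 baseline; `beta1` group effect (treated - control).
#' @param sd_animal,sd_slice,sd_cell random-effect SDs (>= 0).
#' @param metric metric name written into the table.
#' @param method method label written into the table.
#' @param seed integer RNG seed.
#' @return A `hier_sim_config` list.
#' @export
hier_sim_config <- function(n_animals_per_group = 4L,
                            n_slices_per_animal = 3L,
                            n_cells_per_slice = 5L,
                            beta0 = 0,
                            beta1 = 1,
                            sd_animal = 0.5,
                            sd_slice = 0.25,
                            sd_cell = 1,
                            metric = "readout",
                            method = "m1",
                            seed = 1L) {
  if (sd_animal < 0 || sd_slice < 0 || sd_cell < 0)
    stop("all SDs must be >= 0")
  structure(as.list(environment()), class = "hier_sim_config")
}

#' Simulate a nested animal/slice/cell measurement table
#'
#' @param cfg a [hier_sim_config()].
#' @return A data.frame with columns `animal`, `slice`, `cell`, `group`
#'   (`"control"`/`"treated"`), `method`, `metric`, `value` — one row per
#'   cell, balanced per the config.
#' @export
simulate_hierarchical_table <- function(cfg) {
  stopifnot(inherits(cfg, "hier_sim_config"))
  with_seed(cfg$seed, {
    rows <- list()
    k <- 1L
    for (g in 0:1) {
      gname <- if (g == 0) "control" else "treated"
      for (a in seq_len(cfg$n_animals_per_group)) {
        animal <- sprintf("%s_a%02d", substr(gname, 1, 1), a)
        ra <- rnorm(1, 0, cfg$sd_animal)
        for (s in seq_len(cfg$n_slices_per_animal)) {
          rs <- rnorm(1, 0, cfg$sd_slice)
          for (cc in seq_len(cfg$n_cells_per_slice)) {
            rows[[k]] <- data.frame(
              animal = animal,
              slice = sprintf("s%02d", s),
              cell = sprintf("%s_s%02d_c%02d", animal, s, cc),
              group = gname,
              method = cfg$method,
              metric = cfg$metric,
              value = cfg$beta0 + cfg$beta1 * g + ra + rs +
                rnorm(1, 0, cfg$sd_cell))
            k <- k + 1L
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Embed a binary movie into a noisy multi-slice intensity stack
#'
#' Turns a boolean movie into a synthetic acquisition: the mask is painted at
#' `foreground` intensity into the middle optical section of an `n_z`-slice
#' stack over a `background` level, Gaussian noise is added, an optional
#' per-frame exponential bleach is applied, and an optional global
#' translation drift shifts whole frames. Used to exercise the preprocessing
#' chain end to end against a known mask.
#'
#' @param movie a [binary_movie()].
#' @param n_z number of optical sections.
#' @param z_step axial spacing, um.
#' @param foreground,background intensity levels.
#' @param noise_sd additive Gaussian noise SD.
#' @param bleach_rate per-frame multiplicative intensity decay (0 = none).
#' @param drift integer `(dy, dx)` per-frame translation in px (applied
#'   cumulatively), default none.
#' @param seed RNG seed for the noise.
#' @return A [timelapse_stack()].
#' @export
embed_binary_movie <- function(movie, n_z = 3L, z_step = 2,
                               foreground = 0.8, background = 0.1,
                               noise_sd = 0.02, bleach_rate = 0,
                               drift = c(0L, 0L), seed = 1L) {
  stopifnot(inherits(movie, "binary_movie"))
  d <- dim(movie$frames)
  with_seed(seed, {
    data <- array(0, c(d[1], d[2], n_z, d[3]))
    mid <- ceiling(n_z / 2)
    for (t in seq_len(d[3])) {
      fr <- movie$frames[, , t]
      dy <- drift[1] * (t - 1L); dx <- drift[2] * (t - 1L)
      if (dy != 0 || dx != 0) fr <- shift_matrix(fr * 1, dy, dx) > 0.5
      decay <- (1 - bleach_rate)^(t - 1)
      for (z in seq_len(n_z)) {
        sig <- if (z == mid) fr * (foreground - background) else 0
        data[, , z, t] <- pmax(0, (background + sig) * decay +
                                    rnorm(d[1] * d[2], 0, noise_sd))
      }
    }
    timelapse_stack(data, movie$pixel_size, z_step, movie$frame_interval)
  })
}

#' Build a simulator config from a YAML file
#'
#' The YAML must contain a `type` field (`"motility"`, `"chemotaxis"`,
#' `"tree"` or `"hierarchical"`); remaining fields are passed to the matching
#' config constructor. Packaged example configs live under
#' `system.file("extdata/configs", package = "microdyn")`.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's value.
#' @return A simulator config object.
#' @export
sim_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  type <- y$type
  if (is.null(type)) stop("config YAML needs a 'type' field")
  y$type <- NULL
  if (!is.null(seed)) y$seed <- seed
  fun <- switch(type,
                motility = motility_sim_config,
                chemotaxis = chemotaxis_sim_config,
                tree = tree_sim_config,
                hierarchical = hier_sim_config,
                stop("unknown config type: ", type))
  for (nm in c("image_shape", "segment_length_range", "filopodia_length_range",
               "initial_length_range", "lesion_center"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(fun, y)
}
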