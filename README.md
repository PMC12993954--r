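# microdyn

Quantification of microglial process dynamics and structure from
fluorescence imaging, for labs studying microglial surveillance, lesion
chemotaxis, ramification and synaptic engulfment in brain slices.

Microglia continuously survey the parenchyma with a motile, ramified arbor
and converge their processes onto focal damage. `microdyn` implements the
standard measurement chain for both behaviours and for the static state of
single cells:

* **Surveillance index** — from a binarized single-cell movie
  *F*₁…*F*₟, the per-timepoint count of pixels newly gained (extensions,
  PE = |*F*ₜ ∖ *F*ₜ₋₁|) plus newly lost (retractions, PR = |*F*ₜ₋₁ ∖ *F*ₜ|),
  averaged over the movie for one value per cell (pixels per frame
  interval, with a per-30 s rescaling carried for other cadences), plus
  territory area from the first frame.
* **Chemotaxis** — concentric 2 µm rings × 32 radial sectors around a
  lesion centre; per sector, the front is the innermost patch with > 10
  foreground pixels; outputs are per-sector front distances, the enclosed
  polygon area (shoelace), the normalized area curve and its fitted
  convergence rate.
* **Morphometry** — from standard SWC reconstructions: total process
  length, branch points, 3D Sholl curves with trapezoidal AUC
  (half-open sphere-crossing rule), and filopodia (terminal tips with path
  length in [1, 5) µm, per cell and per 10 µm of process); 2D shape
  metrics (area, perimeter, circularity 4π·area/perimeter², F/G-actin
  ratio).
* **Engulfment** — 3D thresholded connected-component scoring of
  lysosomal marker volume (% of cell volume), discrete lysosome counts per
  µm³, and presynaptic puncta inside lysosomes (any-overlap rule).
* **Statistics** — linear mixed-effects models `value ~ group +
  (1 | animal)` (optional slice variance component) for cells nested in
  animals, Sholl AUC summaries, and z-score harmonization across labeling
  methods.
* **Preprocessing** — registration, rolling-ball background subtraction,
  maximum filtering, bleach correction, MIP and recorded thresholding,
  from raw multi-page TIFF stacks to binarized movies.
* **Synthetic data** — generators for every input (movies, SWC trees,
  organelle volumes, nested measurement tables) with exact constructive
  ground truth, so the whole pipeline is verifiable end to end.

## Worked example

```r
library(microdyn)

# a ramified cell surveying for 3.5 min at 30 s cadence
sim <- simulate_surveillance_movie(
  motility_sim_config(image_shape = c(128, 128), n_frames = 8,
                      initial_length_range = c(5, 10), seed = 11))
res <- surveillance_index(sim$movie)
res
#> <surveillance_result> 7 frame pairs, mean index 49.29 px per 30 s
territory_area(sim$movie)
#> [1] 57.25
head(surveillance_table(res), 3)
#>   frame pe pr index
#> 1     2  9 41    50
#> 2     3 30 39    69
#> 3     4 22 33    55
```

The cell turned over on average 49.3 pixels per 30 s frame interval
(extensions plus retractions) and occupied 57.25 µm² in the first frame.
`res$index_per_frame` equals the simulator's recorded changed-pixel counts
exactly.

```r
# processes converging on a 15 um lesion at 2 um/min
cfg <- chemotaxis_sim_config(image_shape = c(360, 360), n_frames = 11,
                             seed = 2)
ch <- simulate_chemotaxis_movie(cfg)
prof <- convergence_curve(ch$movie,
                          polar_grid_config(lesion_center = cfg$lesion_center))
prof
#> <front_profile> 11 frames x 32 sectors; normalized-area rate -0.0885 / min
```

The negative rate is the fitted slope of the front-enclosed area
(normalized to frame 1) per minute: the front contracts toward the lesion.

```r
# morphometrics of a simulated reconstruction
tr <- simulate_tree(tree_sim_config(seed = 5))
morphology_metrics(tr$tree, cell = "cell_01")
#>      cell total_length_um branch_points filopodia filopodia_per_10um sholl_auc
#> 1 cell_01        118.5737             4         5          0.4216788      97.5
```

Group comparisons respect the animal hierarchy:

```r
tab <- simulate_hierarchical_table(hier_sim_config(beta1 = 2, seed = 3))
fit_lmem(tab)          # value ~ group + (1 | animal), REML, Wald z
```

A thin command-line wrapper over these functions is installed at
`system.file("scripts", "microdyn", package = "microdyn")` with
`simulate`, `preprocess`, `surveillance`, `chemotaxis` and `morphology`
subcommands; example simulator configs live in
`system.file("extdata", "configs", package = "microdyn")`.

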