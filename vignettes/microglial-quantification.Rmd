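---
title: "Quantifying microglial dynamics, morphology and engulfment with microdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial dynamics, morphology and engulfment with microdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## The measurement problem

Microglia survey the brain parenchyma with a ramified arbor of fine
processes that extend and retract on a timescale of seconds to minutes, and
they converge those processes onto sites of focal damage. Both behaviours
are routinely quantified from two-photon timelapse imaging of labelled
microglia in acute brain slices, and the resulting per-cell measurements
are compared between treatment or genotype groups in which cells are nested
within brain slices and animals. `microdyn` implements that entire
measurement chain — movie preprocessing, the motility and chemotaxis
statistics, static morphometry from SWC reconstructions, phagolysosomal
scoring, and the hierarchical statistics — together with synthetic-data
generators that produce each input with exact ground truth, so that every
stage can be verified without access to any particular microscope's
recordings.

## Surveillance index

The substrate of the motility analysis is a binarized single-cell movie
$F_1, \dots, F_T$ (one boolean frame per timepoint, after projection and
thresholding). Starting with the second frame, each frame is compared with
its predecessor: pixels present only in $F_t$ are process extensions (PE),
pixels present only in $F_{t-1}$ are retractions (PR). The surveillance
index at timepoint $t$ is $\mathrm{PE}_t + \mathrm{PR}_t$ — the cardinality
of the symmetric difference $|F_t \oplus F_{t-1}|$ — and the per-cell value
is the mean over all $T-1$ frame pairs, with no trimming and no size or
connectivity filtering of the changed pixels. The primary unit is pixels
per frame interval; when the cadence is not 30 s the value rescaled to
pixels per 30 s is carried alongside, so recordings at other cadences stay
comparable (both numbers are always reported rather than silently
converting).

Useful exact properties follow directly from the definition and are tested
as such: reversing time swaps PE and PR but leaves the index unchanged; for
two cells with disjoint supports the index of the union movie is the sum of
the individual indices; and the index can never exceed the frame size.

`territory_area()` reports the foreground area of the first frame in
$\mu m^2$ — a measure of the territory a cell occupies that is by
construction independent of everything after frame 1.

## Chemotaxis: concentric rings and radial sectors

The chemotactic response to a focal lesion is quantified by tracking the
front of converging processes on a polar grid centred on the lesion: rings
of width 2 µm and 32 angular sectors partition the surroundings into
patches. For each frame and each sector, rings are scanned outward from the
centre and the front is the first patch containing strictly more than 10
foreground pixels; the outputs are the per-sector front distance and the
area enclosed by the polygon of front points (shoelace formula over the
sector mid-angles), summarized as the slope of the normalized area over
time.

Two conventions are underdetermined by this description, and both are
exposed as configuration rather than hidden:

* **Where within the qualifying patch is the distance reported?** The
  default is the patch radial midpoint, which makes the quantization error
  symmetric (at most half a ring width in either direction); the inner edge
  is available via `report_at = "inner"`.
* **How do sectors with no qualifying patch enter the area?** They are
  assigned `max_radius` before polygon construction — dropping them would
  leave the polygon ill-defined — and the number of substituted sectors is
  reported with every frame so such frames can be filtered downstream.

The angular origin (+x axis, counterclockwise in array coordinates) is
arbitrary and fixed only for determinism; no reported summary depends on
it. The lesion centre is user-supplied, mirroring practice, with the grid
builder refusing centres outside the image.

## Morphometry from SWC reconstructions

Reconstruction (tracing) itself is out of scope: the package consumes
standard 7-column SWC files and validates them strictly (single root,
resolvable parents, acyclicity), naming the offending line on failure.

* **Total process length** is the sum over non-root nodes of the Euclidean
  distance to the parent.
* **Branch points** are non-soma nodes with at least two children. The soma
  is excluded by default even when several primary processes leave it —
  primary-process origins are not branchings of a process — but the
  alternative convention is one flag away, because this is a genuine
  judgment call in the field.
* **Sholl analysis** counts edges crossing concentric spheres centred on
  the soma. Crossings use the half-open rule ($\min d < r \le \max d$), so
  an edge ending exactly on a sphere is counted once and never twice. The
  radius step defaults to 1 µm (configurable; no canonical value exists),
  and spheres are 3D — reconstructions are 3D objects, and projecting
  before counting would conflate depth with complexity. Radii extend one
  step past the outermost node so the curve always closes on a zero; the
  per-cell summary is the trapezoidal AUC of the curve.
* **Filopodia** are terminal tips whose path length back to the nearest
  branch point or soma falls in the half-open window $[1, 5)$ µm: the
  5 µm upper bound defines these short dynamic branchlets, and 1 µm is the
  reconstruction floor below which tips are not resolved. Path length along
  the tree is used, not the straight-line leaf-to-branch distance, because
  filopodia are curved structures measured along their extent. Counts are
  reported per cell and per 10 µm of total process length.

All of these are invariant under rigid motions of the coordinates, and the
test suite checks this to $10^{-9}$ relative tolerance with random
rotations and translations.

### 2D shape metrics

For cell-culture images, `shape_metrics()` reports mask area, perimeter,
circularity $4\pi \cdot \mathrm{area}/\mathrm{perimeter}^2$, and the ratio
of F-actin to G-actin channel means within the mask. Circularity is
acutely sensitive to the perimeter estimator: the raw marching-squares
contour of a binary mask systematically overestimates the length of
digitized curved boundaries (a digitized disc of radius 50 px comes out
around 6% long, pushing circularity to ~0.89), while lattice-counting
estimators that fix the disc break squares. The package therefore measures
the 0.5-level contour of the mask after Gaussian regularization with
$\sigma = 2$ px, which tracks the underlying smooth boundary: the same
disc then yields circularity 1.000, and a 100 px square yields 0.81
against the continuous-limit $\pi/4 \approx 0.785$. The estimator name is
recorded in every result so values from different tools are never silently
mixed.

## Preprocessing chain

Raw movies pass through a fixed, logged order: XY registration →
rolling-ball background subtraction → maximum filtering → bleach
correction → maximum-intensity projection → thresholding.

* **Registration** is translation-only phase correlation against the first
  frame, estimated on per-frame projections and applied to every optical
  section; slice drift at this magnification is translational, so rotation
  and scale are out of scope. Applied shifts are recorded in the run log.
* **Background** is estimated by grayscale morphological opening with a
  disc of radius 50 px (edge-replicated padding, so a constant image maps
  to exactly zero). Bit-equivalence with any specific legacy rolling-ball
  implementation is not promised; correctness is asserted on constructed
  scenes (spot preservation, gradient removal, `output <= input`).
* **Maximum filtering** uses the discrete disc $dy^2 + dx^2 \le r^2$
  (13 pixels at the default radius 2), enumerated explicitly in the tests.
* **Bleach correction** defaults to mean-ratio normalization to frame 1 —
  the exact inverse of any per-frame multiplicative decay, and sufficient
  because a monotone intensity correction only needs to stabilize the
  threshold. A log-linear exponential-fit mode is available when single
  frames have outlying means. Which mode ran is logged.
* **Thresholding** requires a recorded number: a manual value, or `"auto"`
  for Otsu's criterion computed on the first-frame projection and applied
  to all frames. Either way the realized value lands in the run log,
  because a threshold that is not recorded cannot be reproduced.

One consequence is worth stating plainly: the maximum filter dilates thin
structures by construction, so after the full chain the recovered mask is
the dilation of the underlying one. The round-trip tests therefore compare
against the identically max-filtered ground truth (Jaccard ≥ 0.98, in
practice exact), and exact mask recovery is asserted with the max filter
disabled.

## Organelle and engulfment scoring

Interactive surface rendering is replaced by thresholding plus 3D
connected components: the lysosome-marker channel is binarized (fixed
value, or Otsu within the cell mask), intersected with the cell mask, and
26-connected components of at least 4 voxels are retained. Reported are
the marker volume as a percentage of cell volume, and the discrete
component count normalized to cell volume (per µm³ by default, per voxel
behind a flag, both logged — the normalization convention is not
standardized across studies). Presynaptic puncta are binarized and
labelled the same way (minimum 2 voxels), and a punctum counts as engulfed
when **any** of its voxels overlaps a lysosome component; a stricter
centroid-inside rule is available, and on the packaged fixtures the two
rules differ exactly on boundary-straddling puncta, which is the intended
behaviour. The size-filter defaults (4 and 2 voxels) suppress hot voxels
at typical confocal sampling (0.5 µm z step, 0.1 µm xy) and are
configurable.

Voxels may be anisotropic: volumes are always computed in µm³ from the
per-axis voxel size, while connectivity remains lattice-based in voxel
space — a documented limitation shared with most particle-analysis tools.

## Statistical layer

Cells are not independent: they are nested within slices within animals.
Group comparisons therefore use a linear mixed-effects model,
`value ~ group + (1 | animal)`, fitted by REML, with an optional
slice-within-animal variance component for designs where the treatment is
applied to slices rather than animals. The default p-value is a Wald z
test on the group coefficient (matching the conventional mixed-model
output of the ecosystem this layer interoperates with); a likelihood-ratio
test is available behind a flag. Singular fits — boundary variance
estimates of zero — are reported and flagged, never raised as errors,
because they are legitimate outcomes on small designs; a single animal per
group, by contrast, is a design error and is refused.

Sholl curves are reduced to one AUC per cell before modeling; per-radius
repeated-measures modeling is deliberately out of scope.

When morphology is acquired with different labelling methods, raw values
are harmonized by z-scoring within each method, pooling the cells of both
genotypes: $z = (x - \mu_{method})/\sigma_{method}$ with the $n-1$
denominator. Pooling is the only reading consistent with the purpose of
the transform — standardizing within genotype would erase the genotype
effect being tested — and the per-method $\mu, \sigma$ are attached to the
output. Zero within-method variance is an error naming the method.

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure* the pipeline
consumes, not microglial biophysics:

* `simulate_surveillance_movie()` builds a soma-centred star of processes
  whose tip lengths follow a symmetric two-sided exponential random walk
  with means set by the extension/retraction rates, all multiplied by
  `motility_scale` (the stand-in for a treatment effect). Defaults emulate
  the standard acquisition regime (512×512 px, 30 s cadence, 10 min). No
  published characterization of the temporal statistics of process motion
  exists, so this dynamics model is a documented stand-in: any model with
  tunable magnitude suffices for oracle testing, and the recorded ground
  truth (the exact changed-pixel count per frame pair) is what the
  surveillance metrics are verified against.
* `simulate_chemotaxis_movie()` advances radial processes toward a 15 µm
  circular lesion at a programmed speed, recording the true front radius
  per frame (floored at the lesion radius).
* `simulate_tree()` grows SWC trees with controlled branching and attaches
  a known number of filopodia at internal nodes; with the default backbone
  segment lengths (6–15 µm, above the 5 µm filopodia bound) the programmed
  filopodia count is exact by construction.
* `simulate_organelle_volume()` voxelizes an ellipsoidal cell, disjoint
  lysosome spheres and once-dilated single-voxel puncta, with per-sphere
  voxel counts as ground truth. Puncta flagged "inside" are placed at
  lysosome centres to avoid boundary ambiguity in fixtures.
* `simulate_hierarchical_table()` draws
  $y = \beta_0 + \beta_1 g + a_{animal} + s_{slice} + e_{cell}$ with
  independent zero-mean normal components.

Movies are generated directly as boolean projected movies — the substrate
the metrics are defined on — and `embed_binary_movie()` optionally wraps
them into noisy multi-slice intensity stacks (additive Gaussian noise,
optional bleach and drift) to exercise the preprocessing chain end to end.
Passing tests on these inputs demonstrates that the *measurement code* is
correct and the statistical layer is calibrated; it does not validate any
biological claim about real microglia, whose movies contain structured
noise, neighbouring cells and nonrigid motion that the generators do not
model.

All generators are bit-reproducible: the same config and seed give
identical output regardless of the ambient RNG state.

## Numerical choices and problem sizes

Thresholds binarize with strict `>`; the front-patch qualification is
strict (`> 10` pixels means at least 11). Sholl uses half-open crossing
tests; filopodia use the half-open window. Degenerate inputs are handled
explicitly: all-zero frames register with zero shift and a warning, empty
first frames give zero territory with a warning, empty Sholl curves give
AUC 0 with a flag, all-empty thresholded movies are an error naming the
first frame.

The test and verification suites run the statistical simulations at 200
replicates (8 animals per group × 10 cells), movie oracles on up to
64×64×20 random movies, morphometry on 200 random trees, and the
end-to-end sign check on 20 independent two-group runs of 18 small movies
each — sizes chosen so the whole suite verifies every contract in a few
minutes on one CPU while keeping Monte-Carlo tolerances tight.

## Known limitations

* Registration is translation-only; nonrigid tissue deformation is not
  corrected.
* The per-cell isolation of movies (masking away neighbouring cells) is
  assumed done upstream.
* Single-process trajectory tracking and speeds are not implemented.
* The Sholl step size and the perimeter estimator are conventions; values
  are comparable across datasets only when these settings match, which is
  why both are recorded in the outputs.
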