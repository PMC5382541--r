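---
title: "Connectivity of stratified urban greenspace: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity of stratified urban greenspace: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataconn)
```

## The problem

Two-dimensional greenspace maps — typically an NDVI threshold on optical
imagery — treat all vegetation as one layer. Any connectivity statistic
computed on such a map implicitly assumes that an organism moving through
"green" pixels finds its habitat stratum everywhere vegetation of any kind
is present. Because grass, shrubs and trees each cover only part of the
green surface, this assumption inflates connectivity, and it inflates it
most for organisms confined to a single vertical stratum. `strataconn`
makes the size and the distance-dependence of that inflation measurable.

## From sensor products to binary layers

The pipeline starts from two inputs:

* a **red/NIR reflectance pair** on a common grid, from which NDVI is
  computed as `(nir - red) / (nir + red)`. Where both bands are zero the
  ratio is undefined; the package fills 0 there, which any positive NDVI
  threshold classifies as non-vegetated. A pixel is vegetated iff
  NDVI ≥ `ndvi_min` (default 0.2, inclusive), giving the `green2d` layer.
* a **voxel canopy**: fractional vegetation cover on a 3D grid, by default
  1.5 m × 1.5 m horizontally and 0.5 m vertically, the standard resolution
  of waveform-lidar canopy products. A voxel is vegetated iff its cover is
  at least `cover_min` (default 0.01, i.e. 1 %, inclusive).

Vegetated voxels are assigned to height bands by their **center height**
`base + (k + 0.5) · voxel_height`: grass below `grass_max_h` (0.5 m),
shrub in the closed interval [`grass_max_h`, `shrub_max_h`] (0.5–4 m),
tree above `shrub_max_h` (4 m). Band endpoints for the shrub layer are a
genuinely open design point — "between 0.5 and 4 m" fixes no endpoint
rule — and the center-height convention with a closed shrub interval was
chosen because it assigns every vegetated voxel to exactly one band with
no floating-point ambiguity (centers can never equal a band edge when the
edges are multiples of the voxel height). Heights are above-ground; the
synthetic canopy is generated above-ground, and terrain normalisation of
real data is out of scope.

Each stratum's presence column is projected to the ground and intersected
with `green2d`: a column vegetated at 0.2 m and at 6 m lands in both the
grass and the tree layer (understorey is information a waveform sensor
genuinely provides), while columns the NDVI map calls non-vegetated are
excluded from every stratum. Consequently every stratum mask is a subset
of `green2d` by construction — the formal root of the 2D bias results
below. If the NDVI grid and the voxel grid differ in resolution the NDVI
grid is resampled to the voxel grid by nearest neighbour, which preserves
the semantics of thresholded values; synthetic scenes use matched grids so
no test depends on resampling artifacts.

## Structural metrics

All four metrics are computed from one connected-component labeling of a
layer. Components use **8-connectivity by default** (the common default of
raster landscape-metric software; the adjacency rule is not something the
analysis pins down, so it is exposed as a `neighborhood = 4` option for
sensitivity checks). Labels are assigned in row-major first-pixel order,
making the labeling deterministic.

* **landscape proportion** = Σaᵢⱼ / A;
* **small patch density** = number of patches strictly smaller than 30 m²
  per hectare of landscape ("per total landscape area" fixes no unit, so
  the hectare — the customary unit for patch densities — is used and
  documented here);
* **largest patch index** = 100 · max(aᵢⱼ) / A (percent);
* **connectivity index** CI = 1 − Σ(aᵢⱼ/A)².

`A` is the full raster extent, vegetated or not: CI is the probability
that two pixels chosen uniformly **in the landscape** do not share a
patch, and that sampling frame includes built surfaces. The empty
landscape gets CI = 1, the limit of the probability reading (no pair can
share a patch). These conventions make CI ≤ 1 − (LPI/100)² an invariant,
and the tests verify CI against a Monte-Carlo estimator that literally
samples pixel pairs.

## Functional connectivity

The vegetated surface is buffered outward at every `step_m` (default 1 m)
increment of dispersal distance and CI is recomputed on the buffered map,
up to the first distance at which the landscape is fully covered (CI = 0
exactly). Conventions, each chosen for exact testability:

* **Geometry**: a pixel joins the buffer iff the Euclidean distance
  between pixel centers to the nearest vegetated pixel is ≤ d
  (inclusive). The comparison is done on squared distances — squared
  center offsets are integers, so thresholding is exact in floating
  point, and the implementation (an exact Euclidean distance transform,
  computed once per layer) is bit-identical to brute-force all-pairs
  dilation.
* **No barriers**: buffers expand isotropically over all land cover.
  Barrier-aware movement models are an explicit non-goal.
* **Buffered pixels count as habitat area** in CI at each step; this is
  what makes "fully vegetated map" the natural terminal state.
* **Fixed frame**: CI during buffering uses the same landscape area A as
  the structural metric.
* **Step size** is independent of the pixel size. Sub-pixel steps can
  produce identical consecutive masks; the duplicates are kept so the
  distance axis stays regular.
* **Termination**: a safety cap at the grid diagonal guarantees the loop
  ends; hitting the cap before full cover returns the partial curve with
  `terminated_full_cover = FALSE` and a warning.

`threshold_distance()` reports the smallest sampled distance with CI
strictly below 0.15 — high connectivity, i.e. a greater than 85 % chance
that two random locations are connected. `bias_curve()` differences a
stratum's curve against the 2D curve, padding the shorter curve with
trailing zeros (after full cover CI stays 0); `peak_bias()` returns the
maximum difference, ties broken toward the smallest distance so an
all-zero bias peaks at (0, 0).

Because every stratum mask is nested in `green2d`, and because adding
vegetated pixels can only grow or merge patches ((a₁+a₂)² ≥ a₁² + a₂²),
CI at any buffer distance can only fall when moving from a stratum to the
2D layer. The test suite asserts this inclusion-dominance chain — mask
nesting, pointwise CI dominance, and earlier 2D threshold distances — on
every generated scene, as the formal version of the claim that 2D
greenspace data positively bias connectivity estimates.

## The synthetic-town generator

`generate_scene()` stands in for airborne lidar/hyperspectral surveys.
Each stratum footprint is laid down by dropping random discs until the
target cover is reached; the union of footprints is the green surface.
Choices and what they mean:

* **Fragmentation** (0–1) maps linearly to the mean disc radius, from 8 px
  down to 1.5 px, with per-stratum multipliers (grass 1.6, shrub 0.6,
  tree 1.0) so grass forms broad mats, shrubs small scattered bushes and
  trees intermediate crowns. Radii are drawn uniformly within ±50 % of the
  mean.
* **Covers**: placement stops at the first disc meeting the target, so the
  realized cover overshoots by at most one disc area — within about 0.05
  of the target at 256 px grids and 0.02 at 512 px (tested). Targets above
  0.95 are rejected as impossible for random placement.
* **NDVI**: vegetated pixels draw NDVI uniformly in [0.4, 0.9],
  non-vegetated in [−0.2, 0.1], so the 0.2 threshold separates them with
  certainty while the NDVI arithmetic is still exercised; the red band is
  back-solved from NDVI with NIR fixed at 0.5.
* **Vertical structure**: grass fills the sub-0.5 m level; shrub columns
  fill levels up to a per-pixel bush height in (0.5, 4] m; tree columns
  fill crown levels from above 4 m up to a per-pixel crown top in
  [6, max_height] m. Grass placed independently of trees yields
  grass-under-canopy columns; when both targets exceed 0.2 at least one
  understorey column is guaranteed (if random placement happens to produce
  none, one grass disc is re-centred on a tree pixel, still inside the
  single seeded RNG stream).
* **Buildings and roads** exist only implicitly as low-NDVI, zero-cover
  ground: the connectivity analysis uses vegetation layers only.
* **Archetypes** encode qualitative urban-form contrasts (a planned green
  town, a medieval clustered town, Victorian terraces) as cover and
  fragmentation presets — see `?archetype_params` for the table. They are
  illustrative: no quantitative description of real towns was available
  to calibrate against, so the parameters were fixed once to satisfy the
  qualitative ordering (shrubs sparsest and most fragmented everywhere;
  planned greener and less fragmented than terraced) and are not tuned
  thereafter.

What the generator does **not** emulate: radiometric realism, sensor noise
crossing the NDVI threshold, waveform artifacts, occlusion of understorey
by dense canopy, terrain, seasonal phenology, and spatially correlated
building footprints. Passing tests therefore demonstrate correctness of
the analysis pipeline and of the inclusion/bias structure, not that any
specific real town would yield particular absolute numbers.

## Determinism and problem sizes

Every source of randomness flows from one seed per scene
(`withr::with_seed`), so scenes, pipelines and the JSON run summary are
bit-reproducible; timestamps are kept out of the summary. The shipped
tests run scenes of 48–128 px (plus one 512 px cover-convergence check)
and verify CI against ≥10⁵ sampled pixel pairs per mask and buffering
against brute-force dilation on grids up to 48 px — sizes chosen so the
whole suite completes in well under a minute while every property is
exercised at non-trivial scale. `scripts/acceptance.R` reports means over
three 128 px scenes per archetype.

## Known limitations

* Absolute threshold distances depend on the raster buffer approximation
  (vector-polygon buffers would shift them slightly) and on the adjacency
  rule; both conventions are documented above and the adjacency rule is a
  parameter.
* CI weighs patches by area only; it says nothing about patch shape,
  inter-patch distance distribution, or least-cost movement. Resistance
  surfaces and organism-specific movement simulation are out of scope.
* The stratification is purely geometric (three fixed height bands); no
  species or land-cover classification is attempted.
* The generator's archetypes are qualitative instruments for exercising
  the pipeline, not calibrated urban morphologies.
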