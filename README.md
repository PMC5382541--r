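# strataconn

Urban greenspace is usually mapped in two dimensions: an optical sensor
flags every pixel with NDVI ≥ 0.2 as "green", and landscape connectivity is
computed on that flat map. But organisms do not move through a flat map —
a hedgehog needs connected ground vegetation, a squirrel connected canopy —
and a 2D map silently assumes that grass, shrubs and trees are all present
wherever anything green is. `strataconn` quantifies what that assumption
costs. It stratifies a vegetated scene into grass (< 0.5 m), shrub
(0.5–4 m) and tree (> 4 m) layers by combining an NDVI mask with a
voxelized fractional-canopy-cover grid (the kind of product waveform lidar
delivers, including understorey), computes structural connectivity metrics
per layer, and models functional connectivity for organisms of any
dispersal capacity. It is aimed at landscape ecologists and remote-sensing
scientists working on urban habitat networks.

## The statistic at the core

For a binary layer with patches (connected components) of area
*a<sub>ij</sub>* inside a landscape of total area *A*, the connectivity
index (landscape division index) is

> CI = 1 − Σ (*a<sub>ij</sub>* / *A*)²

— the probability that two randomly chosen pixels of the landscape do not
fall in the same patch. Higher CI means lower connectivity; a single patch
covering everything gives 0, an empty landscape gives 1. Alongside CI the
package reports the landscape proportion Σ*a<sub>ij</sub>*/*A*, the density
of patches smaller than 30 m² (per hectare), and the largest patch index
100·max(*a<sub>ij</sub>*)/*A*.

Functional connectivity buffers the vegetated surface outward by every
1 m increment of dispersal distance *d* (exact Euclidean
center-to-center distances, inclusive) and recomputes CI on the buffered
map until it is fully connected. The curve CI(*d*) reads as "how connected
is this layer for an organism that can cross *d* metres of non-habitat";
CI < 0.15 is taken as high connectivity (> 85 % chance two random
locations are connected). Differencing a stratum's curve against the 2D
curve gives the bias an analysis pays for ignoring vertical structure.

A seeded synthetic-town generator (three urban-form archetypes with
controllable cover, fragmentation and grass-under-tree overlap) emulates
the reflectance and voxel inputs, so the entire pipeline is testable
without airborne survey data.

## Worked example

```r
library(strataconn)

cfg   <- archetype_params("terraced", 64, 64, seed = 3)
scene <- generate_scene(cfg)
masks <- stratify_scene(scene$reflectance, scene$canopy)

do.call(rbind, lapply(masks, structural_summary))
#> # A tibble: 4 × 5
#>   layer   proportion small_patch_density_per_ha lpi_percent    ci
#> 1 green2d     0.315                        7.60        9.55 0.986
#> 2 grass       0.184                        0           4.76 0.993
#> 3 shrub       0.0620                      15.2         1.34 1.000
#> 4 tree        0.105                        0           2.12 0.999

curves <- lapply(masks, functional_curve)
vapply(curves, threshold_distance, numeric(1))
#> green2d   grass   shrub    tree
#>      11      21      16      23

peak_bias(bias_curve(curves$tree, curves$green2d))
#> distance_m      delta
#>      9.000      0.704
```

Read: the flat 2D map covers 31.5 % of this synthetic terraced town and
looks reasonably connected (CI 0.986, high connectivity reached at an 11 m
dispersal distance), but no single stratum is anywhere near that — an
organism confined to tree canopy needs a 23 m dispersal capacity for the
same level of connectivity, and the 2D analysis overstates its
connectivity most strongly (ΔCI = 0.704) at a 9 m dispersal distance.

`run_pipeline()` chains the whole analysis and writes masks, tidy CSV
tables, plots and a deterministic JSON summary; `inst/cli/strataconn.R`
exposes it as a command-line tool with `simulate`, `stratify`, `metrics`,
`funconn` and `run` subcommands.

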