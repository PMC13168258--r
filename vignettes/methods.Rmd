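---
title: "Methods: scenario construction and social profiling on an equal-area grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario construction and social profiling on an equal-area grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conserve30)
```

`conserve30` asks a social question about a spatial-planning exercise: if
protected and conserved areas were expanded from their current extent to 30%
of land under different prioritization logics, who would live inside and
near the selected areas? This vignette documents the models and procedures
the package implements, the parameters that matter, the synthetic world the
tests run on, and the numerical choices made where more than one convention
was defensible.

## The grid contract

Everything happens on a planar equal-area grid of square cells
(`grid_spec()`, default 5 km side, 25 km² cells). The equal-area property is
the only geometric fact the analysis relies on: areas are cell counts times
the constant cell area, and coverage fractions are cell-count ratios. A
global analysis would use an equal-area projection such as Mollweide; the
package is agnostic about which frame the coordinates live in, it only
requires that cells have equal area. Latitude, needed for the ±24° tropics
band, is carried as a per-row coordinate, which on the synthetic world is a
simple linear north–south axis. Cell indexing is row-major and 0-based with
cell (0,0) at the origin corner; all documented tie-breaks refer to this
ordering.

Coverage rasterization (`rasterize_coverage()`) computes, per cell, the
fraction of cell area under the *union* of the input polygons, by a scanline
sweep: each cell row is cut into `n_sub = 64` horizontal strips, the
interior x-intervals of every polygon on the strip midline are found by
even-odd crossing counting, unioned, and their exact lengths accumulated.
The result is exact in x and discretized in y; against an independent
100×100 point-sampling oracle the per-cell error stays well inside 0.01
(the package's stated accuracy contract, checked in the test suite).
Self-intersecting or degenerate polygons are rejected with their record id.

Other conventions of the grid engine:

- `threshold_mask()` is **inclusive**: a cell with exactly 50% coverage is
  classified protected/conserved. Nodata never qualifies.
- `regrid()` aggregates factor×factor blocks by sum, mean, or mode. Sums are
  conserved bit-for-bit at integer inputs; nodata cells are excluded from
  sums and means everywhere in the package, and an all-nodata block stays
  nodata. **Mode ties break to the lowest category code** so categorical
  aggregation is deterministic.
- `buffer_mask()` uses cell-center Euclidean distance in the planar frame:
  the ring contains the cells outside the mask whose center lies within the
  buffer distance of some mask-cell center. Published global analyses do not pin
  down the cell-level discretization of a "10 km buffer"; a vector-space
  buffer rasterized afterwards would be equally defensible, and the
  cell-center rule was chosen because it is exactly reproducible and makes
  ring/mask disjointness and nesting in distance provable invariants.
- `zonal_weighted_mean()` signals an undefined result (`NA` with a warning)
  when the total weight is zero instead of silently returning 0.

## Protected-area baseline

`filter_records()` applies the register-style rules in a fixed order, each
record receiving exactly one audit line: negative reported areas are
rejected; proposed-status **PAs** are dropped, while OECMs are kept whatever
their status flag; MAB biosphere reserves are dropped (PA category only —
the rule is not extended to OECMs); marine-realm records are dropped; point
records with a reported area A become regular 64-gons centred on the point
whose circumradius is scaled so the polygon area equals A exactly (a plain
circumradius of √(A/π) would undershoot the area by ~0.16%); point records
without an area are discarded rather than guessed. `build_baseline()` then
rasterizes the kept geometries, zeroes coverage outside the land mask (the
grid-level equivalent of clipping away marine portions of coastal sites),
and applies the inclusive 50% threshold.

## Scenario builders

All three builders share `scenario_config()`: a total coverage target
(default 0.30 of land), an ecoregion representation target (0.15), an HMI
intactness cutoff (0.1), a replicate count and a seed. The cell budget is
`round(target × land cells)`, so achieved coverage is always within one cell
of the target — a property the test suite asserts for every scenario.

**Biodiversity.** Conservation features carry a per-cell amount (km²) and a
target amount. Species targets follow the standard range-size rule: full
representation below 1,000 km² of area of habitat, 10% above 250,000 km²,
log-linear in between. Ecoregions get 15% of their area. The selection
minimizes the weighted sum of proportional shortfalls
Σ\_f w\_f·max(0, t\_f − h\_f)/t\_f with the baseline and all key biodiversity
areas locked in. The exact solver used at global scale in the literature is
an integer program; this package instead ships a fully specified greedy
heuristic — repeatedly add the candidate cell with the largest marginal
objective decrease, ties row-major, stop early when no cell helps — plus a
variable-depth exchange refinement (best-improvement 1-for-1 swaps, then
2-for-2 exchanges on small instances, with capped neighborhood sizes so
scenario-scale runs stay fast). The choice is deliberate: the objective is
the scientific content and is fully specified; the solver is infrastructure.
`min_shortfall_enumerate()` solves instances of up to ~20 candidate cells
exactly by enumeration, and the test suite requires the heuristic to match
it on 100 randomized instances. Zero-target features are excluded from the
objective with a warning (their proportional shortfall is undefined). If the
greedy selection saturates every attainable target before the budget is
spent, the remaining budget fills in row-major order so the coverage target
is still met; with no features at all this degenerates to pure row-major
filling, which is documented rather than an error.

**NCP.** The baseline is assigned infinite priority, then land cells are
taken in descending rank until the target is reached, final partial step
row-major. The captured value share is computed on the original rank (before
the baseline override) so it measures how much of the total rank value the
selection holds.

**ITT.** The builder follows five steps: buffer point-format ICCA records to
their reported area (reusing the register logic); drop territory geometries
flagged "subject to other special rights"; rasterize the ICCA and territory
geometries jointly (union coverage) and unite the thresholded cells with the
baseline; exclude candidate cells above the HMI cutoff; and, if coverage
still exceeds the target, remove eligible cells uniformly at random until it
is met. ICCA and baseline cells are never removed and are **exempt from the
HMI filter**: applying the filter to the baseline would shrink the current
network below its own coverage, contradicting the premise that scenarios
extend it. Replicate r draws from `seed + r`; the reported mask is replicate
1 (an arbitrary but fixed choice), the inclusion-frequency layer is the
per-cell mean across replicates, and `profile_replicates()` averages
downstream statistics across replicates. `coarsen_frequency()` provides the
privacy-preserving coarse display (any touched coarse block is "present")
used when territory boundaries are too sensitive to map at full resolution.

## Social profiler

`social_profile()` computes, for any mask: the resident population; the
population of the buffer ring (default 10 km; 5 and 15 km are the standard
sensitivity values); population by HDI class; population-weighted mean HDI;
the wild-harvesting share of the *tropical* resident population (the source
wild-harvest layers exist only between 24°N and 24°S, so the denominator is
restricted accordingly and the tropical resident count is reported
alongside); farm-size class area shares of the mask; the livestock-only
rangeland share; and population growth between the two epochs.

The HDI class bounds are printed in the literature both as
"0.550–0.699 / 0.700–0.799" and as "0.55–0.70 / 0.70–0.80"; the package uses
half-open intervals [0, 0.55), [0.55, 0.70), [0.70, 0.80), [0.80, 1], which
reconciles both notations and guarantees the class populations partition the
resident population over cells with defined HDI — an invariant in the test
suite. Mean HDI is population-weighted, not area-weighted, because the
question is about people, not places. Farm and rangeland statistics are area
shares (the sources report area for these); buffer populations of
overlapping scenarios are reported per scenario without de-duplication.

`overlap_analysis()` takes the three scenarios' *new* cells (the caller must
subtract the baseline; passing masks that still contain baseline cells is an
error) and reports each scenario's unique fraction, pairwise overlaps in
both directional forms |A∩B|/|A| and |A∩B|/|B| plus the symmetric Jaccard
ratio — the printed overlap percentages in the literature do not state their
denominator, so all three are emitted rather than guessing — the
triple-shared fraction of the union of new cells, and the fraction of land
in no scenario and not in the baseline.

`sensitivity_sweep()` re-runs the profile over named layer substitutions and
buffer distances, skipping (with a logged reason) any substitute that is not
on the common grid. It accepts any mask, so alternative scenario layers plug
in as substitutes without special handling.

## The synthetic world

`generate_world()` produces a deterministic world from a single seed routed
through named substreams (one `set.seed(seed + offset)` per component), so
adding draws to one component never perturbs another. Defaults: a 60×60 grid
of 5 km cells (~3,600 cells, generated in well under a second; tests and the
acceptance script use this size throughout, with a 40×40 variant in the
pipeline tests), 85% land from a thresholded smooth field, and rows spanning
60°S–60°N so the tropics band covers 40% of rows.

What the generator emulates, and how:

- **Population** is built on a 5×-finer grid (1 km cells, like the
  harmonised settlement rasters it mimics) as Gaussian-kernel clusters with
  log-normal masses over a thin rural background, then sum-aggregated — so
  the aggregation path of real data processing is exercised end-to-end.
- **HDI** is a linear (clipped to [0.02, 0.98]) map of
  ρ·z + √(1−ρ²)·noise, with z the standardized log population density and
  the noise spatially smooth; the linear map preserves the target Pearson
  correlation ρ (default 0.8, realized within ±0.1 across seeds — a tested
  contract), which a logistic squash would attenuate.
- **HMI** saturates in population density (1 − exp(−density/25 persons km⁻²))
  plus small smooth noise, so remote land is intact and settled land is
  modified, coupling modification to settlement as in the real layers.
- **Wild harvesting** is population × rate(HDI) inside the tropics, with
  rate = 0.2·exp(−3·(HDI − 0.5)) capped at 1 — concentrated in the low-HDI
  tropics, zero elsewhere, never exceeding population.
- **Territories** are circular blobs placed preferentially on intact
  (HMI ≤ 0.1), below-median-HDI land, twice as likely in the tropics
  (mirroring where custodian lands predominantly are), and sized
  (12 blobs, log-normal around 4,500 km²) so the pre-trim territory union
  reliably exceeds the 30% target — the situation the trimming step of the
  ITT builder presumes (the real pre-trim layer covered 36%). One territory
  carries the "subject to other special rights" flag to exercise the
  exclusion; ICCA records alternate polygon and point format to exercise
  buffering.
- **NCP rank** is intact supply times beneficiary demand
  (0.15 + 0.85 × normalized smoothed log density) plus smooth noise —
  "realized benefits weighted by beneficiaries" — which places NCP
  priorities near, but not inside, settled areas and keeps NCP–ITT overlap
  low, as published global overlap figures suggest.
- **Species** areas of habitat are geometric blobs with log-uniform sizes in
  [200, 400,000] km² (capped at 60% of land); **ecoregions** and
  **continents** are seeded Voronoi partitions; **KBAs** small blobs; the
  **protected-area records** include one of each tricky register case
  (proposed, MAB, marine, point-with-area, point-without-area) on top of
  ordinary polygons sized so the baseline lands near a sixth of land.
- **Growth** to the second epoch is faster where HDI is low
  (rate 0.30·(1 − HDI) plus noise), and the **farm-size / livestock**
  layers tile each cell deterministically from density and HDI.

`plant_contrast()` then plants a known social signature: HDI is lowered by
0.2 (clipped to [0, 1], with clip counts recorded in the world's `truth`)
and the wild-harvest rate re-derived from the lowered HDI and doubled,
inside the custodian lands — specifically in the intact (HMI ≤ 0.1) parts of
the broad territory polygons and throughout the ICCA geometries. Restricting
the broad-polygon planting to intact cells matters: territory fringes near
settlements are precisely the cells other scenarios pick up through their
population affinity, and the planted signature belongs to the custodian
heartlands that the ITT scenario can actually contain. The recovery property
— the profiled territories scenario showing the lowest population-weighted
mean HDI and the highest wild-harvest share of the three scenarios in at
least 95% of 50 seeded worlds — is checked in the test suite and
recomputed by the acceptance script.

What the synthetic world does **not** emulate: real geography and
contiguity, calibration to real global totals, coastlines or inland-water
distinctions, spherical geometry, data gaps and reporting artifacts of real
registers, or the spatial autocorrelation structure of any particular
product. Passing tests therefore demonstrate that the *pipeline* computes
the intended quantities under the assumed statistical structure — not that
the structure matches any particular real dataset.

## Numerical choices and degenerate inputs

- Tie-breaks are row-major everywhere a selection is otherwise ambiguous
  (greedy additions, exchange refinement, NCP partial step, budget
  padding).
- The enumeration solver returns the lexicographically first optimum and
  exploits the objective's monotonicity (adding cells never increases it) to
  enumerate only maximal subsets; it refuses instances beyond 25 candidate
  cells.
- Objective comparisons use an absolute 1e-12 slack; the exchange
  refinement only accepts strictly improving moves, guaranteeing
  termination.
- Degenerate inputs have defined behaviour rather than crashes: empty record
  lists give zero coverage; an empty mask buffers to an empty ring; a
  zero-weight zonal mean is `NA` with a warning; zero-target features are
  excluded with a warning; an over-target locked-in area, an all-nodata
  rank, and a territory scenario whose non-removable area exceeds the target
  are errors naming the excess.
- External formats are plain text: ESRI ASCII grids for layers and masks
  (readable by any GIS raster engine) and GeoJSON for geometry and record
  lists. No binary raster format is written because no suitable writer is
  available in the package's dependency footprint, and the text formats
  carry the full information at these problem sizes.

## Pipeline reproducibility

`run_pipeline()` executes the stages in dependency order, caching each
stage's result keyed by a hash of its configuration section and its
upstream keys: re-running an unchanged configuration is pure cache hits with
byte-identical outputs, corrupting a cached stage triggers recomputation of
it and its descendants, and the manifest lists every output file with a
content hash. Determinism given seed and configuration is asserted in the
test suite.

## Known limitations

- The grid engine is adequate for desk-scale grids (10⁴–10⁵ cells); it is
  not an optimized raster backend and a ~90,000-cell world is the intended
  upper end for interactive use.
- The greedy-plus-exchange heuristic is exact on the tested small-instance
  distribution but carries no optimality certificate at scale; the
  literature's 1%-gap integer programming result is the reference at global
  size.
- Buffer rings are cell-center discretizations; sub-cell buffer geometry is
  out of scope.
- Profiles carry no uncertainty intervals (comparable published analyses
  report none); the territories scenario's replicate spread is the only sampling
  variability surfaced.
- Country-level disaggregation is deliberately absent; continents are the
  finest reporting unit.
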