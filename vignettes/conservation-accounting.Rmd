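---
title: "Spatial conservation accounting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial conservation accounting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatcons)
```

This vignette documents the models implemented in `spatcons`, the
assumptions behind them, the numerical conventions, and the design
decisions that were genuinely open. It is the reference for anyone who
wants to know *why* the package computes what it computes.

## The accounting model

All analysis happens on one abstract grid per run (`grid_spec`): a
matrix of cells with per-cell area weights in km² and a land mask. The
grid is equal-area by default; a full area-weight matrix is the escape
hatch for latitude-varying cells, since real "1-km" global grids are
never exactly equal-area and the projection underlying any given source
is often unstated. Every layer — binary template masks, reserve-network
footprints, continuous quality/pressure/CVI surfaces, zone partitions —
conforms to that grid, and anything declared terrestrial is false (or
missing) over ocean by construction.

**Coverage** of a network over a stratum is
`100 · area(mask ∩ stratum) / area(stratum)`, with terrestrial area in
both numerator and denominator; ocean cells never enter. The uplift
from counting biosphere reserves (BRs) alongside protected areas (PAs)
and OECMs is the percentage-point difference after unioning the BR mask
in — a union, so overlap is never double counted, and uplift is
non-negative by construction. Threshold flags against 17% and 30% use
`≥`, so a stratum exactly at a target counts as meeting it.

**Representativeness** of a binary opportunity template is the percent
of the template's area inside a network. The baseline for judging it is
the network's own share of global land: a network scattered uniformly
at random over land captures, in expectation, exactly its land share of
any fixed template, so representativeness above that share indicates
deliberate spatial alignment. The suite verifies this null calibration
by Monte Carlo.

**The Conservation Value Index.** Template *i* covering land-area share
$p_i \in (0, 1]$ receives the rarity weight

$$w_i = \frac{1/p_i}{\sum_{j=1}^{n} 1/p_j}, \qquad \sum_i w_i = 1 ,$$

and each land cell scores $\mathrm{CVI} = \sum_i w_i R_i$ where
$R_i \in \{0,1\}$ is the cell's membership in template *i*. CVI is
bounded in $[0, 1]$, hitting 1 only where a cell intersects every
template. For binning, the surface is min–max standardized across all
terrestrial cells. One subtlety: the standardization is described in
sources of this kind both as part of the index definition and as a
separate post-processing step; it is a single idempotent-in-intent
operation and the package applies it once.

**Prioritization.** Provinces are summarized by (a) coverage of the
combined BR∪PA∪OECM network and (b) the area-weighted mean of the
standardized CVI, then binned independently into empirical sextiles.
Priorities are provinces in the Q5–Q6 value × Q1–Q2 coverage cells of
the 6 × 6 matrix. A pressure surface (Human-Footprint-like, 0–50) is
summarized per province by area-weighted zonal mean as context for how
feasible conventional strict protection would be.

**Trends.** Each reserve's annual mean habitat quality (a [0, 1] index
consumed as input rasters) is extracted over its footprint starting
five years before designation — capturing preparatory management — but
never before the stack's first year; with a stack starting in 1992,
reserves designated in 1997 or earlier start in 1992. Strata are
aggregated by unweighted mean across reserves (each reserve counts
once; an area-weighted variant is available via the `weights` argument
because the choice is not forced by anything structural). Separate OLS
regressions per sub-period give slope, two-sided t-test p-value, 95%
CI and significance stars (\* p<0.05, \*\* p<0.01, \*\*\* p<0.001).
The default sub-periods are 1992–2000, 2001–2010 and 2011–2020; the
alternative phrasing "2000–2020" that sometimes accompanies such
analyses is ambiguous about boundaries, so the explicit triplet wins
and the boundaries are configurable.

## Numerical conventions

- **Cell membership is center-in-polygon** (even-odd rule, holes
  subtract), not any-overlap: unbiased at fine resolution and exactly
  the semantics of a binary mask. Rasterization error for a disc of
  diameter *d* cells scales like 1/*d*; the suite asserts < 5% area
  error at ≥ 20-cell diameters and decreasing mean error under
  refinement.
- **Circular buffers** for reserves without polygons use radius
  $\sqrt{A/\pi}$ and are realized as 64-gons inflated to the exact
  target area (a raw inscribed n-gon under-covers by
  $n \sin(2\pi/n)/2\pi$). Buffers are *not* clipped to land when sized;
  the land intersection happens at accounting time, which mirrors how
  reported terrestrial areas drive buffer sizes in practice.
- **Top-decile hotspots** select cells at or above the area-weighted
  90th-percentile value of each layer, then intersect across layers.
  Boundary ties are *included* (`≥`), so the realized share can exceed
  0.10 under heavy ties; the realized share is what gets reported.
  Deterministic and conservative.
- **Sextile binning** is rank-based: rank *r* of *N* (ascending) maps
  to bin $\lceil 6r/N \rceil$, with ties broken by stable id order and
  a warning. Interpolation-based empirical quantiles differ only at
  ties and were rejected for determinism. Rank-based binning also makes
  the priority selection invariant under monotone transforms of either
  variable — which is why it is immaterial whether raw or standardized
  CVI feeds the province value.
- **Degenerate standardization** (max = min) maps everything to 0 with
  a loud flag instead of NaN, so downstream binning still runs.
- **Zero-share templates** make the rarity weight undefined; the
  default is an error naming the template, with an explicit
  `zero_share_policy = "drop"` that excludes and renormalizes (logged).
- **Missing data** use a single NA sentinel, excluded from every mean
  and area; percentages are carried on the 0–100 scale throughout.
- **Exclusion rules** at reserve load (status "proposed"; PA/OECM rows
  whose designation label merely mirrors a MAB listing) are evaluated
  independently, so the surviving set is order-independent.
- Dominant-biome classification breaks exact area ties toward the
  lowest biome id.

## The synthetic-world generator

`world_config()` defines the study conditions; `gen_synthetic_world()`
realizes them with full ground-truth bookkeeping. What it emulates, and
how:

- **Land** is the top fraction of an autocorrelated Gaussian field
  (box-blurred noise, three passes ≈ Gaussian kernel), hitting the
  requested land fraction to within one cell. The default 0.3 mirrors
  the roughly 29% terrestrial share of the Earth's surface.
- **Provinces / regions / biomes** are contiguous partitions grown by
  seeded multi-source region growth; disconnected land components fall
  back to nearest-seed assignment. Defaults: 20 provinces (scaled down
  from the ~185-unit biogeographical classification to suit a
  100 × 100 grid), 5 regions, 6 biomes.
- **Templates** threshold smoothed noise at the area-weighted quantile
  hitting each target share (realized share within ±0.01). Default
  targets use the printed global shares where published — hotspots
  0.025, phylogenetic-diversity 0.1286, functional-diversity 0.1447 —
  and plausible values for the rest, ordered so risk ecoregions are the
  largest template and indigenous lands second, matching their
  qualitative ranking.
- **Reserves** get log-normal areas and blobby polygons (discs with
  smooth radial perturbation, rescaled to exact area); a configured
  fraction is emitted as centroid+area only to exercise the buffering
  path (default 26% of BRs, the complement of the ~74% of reserve area
  that typically has true polygons). Inter-network overlap is steered
  by a feedback rule — each new reserve is centered inside the union of
  earlier networks iff that keeps the running overlap fraction closer
  to the target — which is simple and auditable; a zero target is
  enforced strictly by rejection-resampling and errors if infeasible.
  Default network sizes put PA∪OECM coverage in the mid-teens of
  percent and the BR land share near 5%, the regime the accounting is
  designed for.
- **Quality stacks** add, inside reserve footprints, a
  piecewise-linear-in-year signal with per-reserve sub-period slopes
  (defaults on the order of 10⁻³ quality units/year) over a static
  smooth background, plus optional cell-level Gaussian noise, clipped
  to [0, 1]. Cells covered by several reserves follow the
  first-generated one; the recorded true slope of a reserve is the
  area-weighted mean of its footprint cells' slopes, which makes
  noiseless recovery exact even under overlap.
- **Determinism**: one root seed is split into fixed per-component
  substreams, so adding a component never perturbs the others, and two
  runs with one config are byte-identical — the full pipeline asserts
  this on its output checksums.

What the generator does **not** emulate: realistic biogeography
(coastlines, latitudinal gradients, climate structure), skewed
real-world reserve size distributions spanning six orders of magnitude,
political boundaries, spatially autocorrelated *noise* in quality
(noise is i.i.d. per cell-year), and any correlation between templates
beyond what shared smoothing scales induce. Passing tests therefore
demonstrate the correctness of the accounting arithmetic and estimators
under known ground truth — not that real-world headline numbers would
be reproduced, which requires the real boundary and template data.

## Problem sizes

Tests and examples run on grids from 10 × 10 (hand-checkable toys) to
200 × 200 (CVI oracle comparison), with Monte Carlo sizes of 100–500
replicates — sizes chosen so the whole suite completes in about a
minute while keeping Monte Carlo standard errors well inside the
asserted tolerances.

## Interface notes

The package is library-first: `run_full_pipeline()` plus the exported
stage functions are the orchestration surface, and
`scripts/acceptance.R` shows the canonical batch entry point. Tables
are CSV; vector data are WKT-in-CSV or GeoJSON; rasters are plain-text
grids (`write_layer_csv`) or single-band 32-bit TIFF for [0, 1]
surfaces (`write_layer_tiff`). The exit behaviour on failure is a
single R error naming the failed stage; cross-module consistency checks
(overlay counts vs. the sum of template indicators; land-mask
representativeness vs. global coverage) run at the end of every
pipeline run.

## Known limitations

- Rasterization is O(bbox cells · ring vertices) per polygon; the
  engine targets desk-scale grids (≤ 1000 × 1000), not the real 1-km
  global grid.
- Geometry support is polygons with holes, discs and buffers — no
  multipolygons, no reprojection.
- The pressure surface and quality stacks are consumed as given; the
  package does not model pressure or recompute habitat-quality from
  land cover.
- Trend comparisons across strata inherit the usual caveats of
  unbalanced panels: per-year reserve counts change as series start in
  different years, and the unweighted mean weights small and large
  reserves equally.
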