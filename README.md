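# spatcons

Spatial conservation accounting on abstract equal-area grids.

`spatcons` is an R package for area-based conservation accounting of the
kind used to evaluate what biosphere reserves (BRs) would add to the
global protected-area network. It answers, on gridded landscapes, the
questions a conservation-planning analyst asks when a third network is
overlaid on protected areas (PAs) and other effective area-based
conservation measures (OECMs):

- **Coverage uplift** — how much does conserved-area coverage rise, per
  region / ecosystem / country / biogeographical province, when BRs are
  counted alongside PAs and OECMs, and which strata cross the 17%
  (Aichi) and 30% ("30×30") thresholds?
- **Representativeness** — what fraction of a binary *opportunity
  template* (biodiversity hotspots, risk ecoregions, phylogenetic- and
  functional-diversity hotspots, high biomass carbon, indigenous lands)
  falls inside each network, compared with the network's own land share,
  which is what a spatially random placement would capture?
- **Conservation Value Index (CVI)** — a rarity-weighted multi-template
  overlay score. Template *i* with global land-area share
  *p<sub>i</sub>* gets weight

  &nbsp;&nbsp;&nbsp;&nbsp;*w<sub>i</sub>* = (1/*p<sub>i</sub>*) / Σ<sub>j</sub> (1/*p<sub>j</sub>*),&nbsp;&nbsp;Σ *w<sub>i</sub>* = 1,

  each cell scores CVI = Σ *w<sub>i</sub>* *R<sub>i</sub>* with
  *R<sub>i</sub>* ∈ {0, 1} its template membership, and the surface is
  min–max standardized over land.
- **Expansion priorities** — provinces are binned into empirical
  sextiles (Q1 lowest … Q6 highest) of conservation value and of
  existing coverage; priorities are the high-value (Q5–Q6) ×
  low-coverage (Q1–Q2) cells of the 6 × 6 matrix, with a
  Human-Footprint-style pressure surface summarized per province.
- **Habitat-quality trends** — per-reserve annual mean quality series,
  aligned to start five years before designation, fitted with separate
  OLS regressions on the 1992–2000 / 2001–2010 / 2011–2020 sub-periods,
  with significance stars (\*p < 0.05, \*\*p < 0.01, \*\*\*p < 0.001).

Because the real global inputs (UNESCO/WDPA boundaries, published
template layers, InVEST quality maps) are large external downloads, the
package ships a seeded **synthetic-world generator** that emulates their
statistical structure — land mask, contiguous province partitions,
autocorrelated binary templates with target shares, three reserve
networks with controlled overlap and buffer-only records, quality stacks
with known piecewise trends — together with ground-truth bookkeeping, so
the entire pipeline is exercisable and testable offline.

## Worked example

```r
library(spatcons)

w <- gen_synthetic_world(world_config(seed = 42))
nm <- w$truth$network_masks
pa_oecm <- union_masks(nm$PA, nm$OECM)

coverage_report(pa_oecm, nm$BR)
#>   stratum pct_without pct_with uplift_pts meets17_without meets17_with ...
#> 1  global       12.93     15.5      2.567           FALSE        FALSE
```

Counting the biosphere-reserve network raises global coverage from
12.93% to 15.50% of land in this world — a 2.57-point uplift, still
short of the 17% flag. The rarity weights invert the template shares:

```r
rarity_weights(w$templates)
#>       BH       RE       PD       TF       BC       IL
#> 0.596998 0.049750 0.115997 0.102931 0.074625 0.059700
```

The rarest template (BH, 2.5% of land) dominates with weight 0.597; the
commonest (RE, 30%) gets 0.050; the six weights sum to one. Priorities
combine the standardized CVI with network coverage per province:

```r
cvi <- minmax_standardize(cvi_surface(w$templates))
summ <- province_summaries(cvi, union_masks(pa_oecm, nm$BR),
                           w$provinces, pressure = w$pressure)
select_priorities(summ)   # priority == TRUE rows:
#>           name coverage_pct value mean_pressure coverage_bin value_bin
#> 5  province_05            0 0.172          30.6           Q1        Q5
#> 7  province_07            0 0.153          20.3           Q1        Q5
#> 15 province_15            0 0.910          24.4           Q1        Q6
```

Three of the twenty provinces are uncovered (Q1) yet rank in the top
sextiles of conservation value, so they are flagged for expansion; their
mean pressure scores (on the 0–50 surface) indicate how human-dominated
each candidate is. `run_full_pipeline()` chains all stages —
simulation, reserve resolution, coverage, representativeness, overlay
meta-analysis, CVI, prioritization, trends — and writes every table
plus a checksummed manifest to an output directory.

## Package layout

| Area | Functions |
| --- | --- |
| Grid engine | `grid_spec`, `binary_layer`, `continuous_layer`, `zone_partition`, `rasterize_polygon`, `union_masks`, `mask_area`, `zonal_mean`, `zonal_fraction` |
| Reserves | `load_reserves`, `circular_buffer`, `resolve_geometries`, `classify_ecosystem`, `network_mask` |
| Coverage | `coverage_report`, `coverage_uplift`, `threshold_flags` |
| Templates | `template_layer`, `template_set`, `template_share`, `top_decile_intersection`, `representativeness`, `overlay_multiplicity` |
| CVI / priorities | `rarity_weights`, `cvi_surface`, `minmax_standardize`, `province_summaries`, `sextile_bins`, `select_priorities` |
| Trends | `quality_stack`, `reserve_series`, `aggregate_series`, `piecewise_trend`, `significance_label` |
| Synthetic worlds | `world_config`, `gen_world`, `gen_templates`, `gen_reserves`, `gen_quality_stack`, `gen_pressure`, `gen_synthetic_world` |
| Orchestration / IO | `run_config`, `run_full_pipeline`, `write_layer_csv`, `write_layer_tiff`, `write_reserves_csv`, `reserves_to_geojson` |

See `vignettes/conservation-accounting.Rmd` for the methods account:
model assumptions, parameter choices, numerical conventions and known
limitations.
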