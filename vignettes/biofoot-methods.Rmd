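---
title: "Methods: landscape biodiversity footprints of cocoa cultivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape biodiversity footprints of cocoa cultivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofoot)
options(biofoot.log_level = "error")
```

## The model

`biofoot` quantifies where a cultivated commodity (cocoa is the worked
case) erodes biodiversity across a landscape, and who along the export
supply chain that erosion should be attributed to. The chain of reasoning
is:

1. **Land-use harmonization.** A categorical land-cover base map plus
   support layers (crop presence, forest management, forest integrity,
   livestock density, potential natural vegetation) are converted into a
   nine-class land-use raster by priority-ordered allocation: cocoa first
   (it is the pressure under study), then other agriculture, then pasture
   (greedy by suitability up to a national area budget), then the four
   forest classes, then residual vegetation, then built-up. Later steps
   never overwrite earlier ones, so allocation is a partition of the
   valid cells.
2. **Intactness.** Mean species abundance (MSA) is a cell-level index in
   [0, 1]: 1 means the original species assemblage is intact, 0 means it
   is locally gone. Three pressures enter multiplicatively,
   `MSA = MSA_lu × MSA_infra × MSA_frag`:
   a land-use response table, a road-proximity banding, and a
   fragmentation response that is piecewise-linear in log10 of the
   4-connected natural-habitat patch area.
3. **Counterfactual.** The cocoa-attributable intactness loss of a cell
   is `MSA_nv − MSA`, where `MSA_nv` is recomputed after replacing every
   cocoa cell with primary forest (the pre-cultivation reference). Roads
   are retained in the counterfactual: only land use changes.
4. **Importance.** Rarity-weighted richness (RWR) sums, over species, the
   fraction of each species' global range falling in a cell (after
   elevation filtering against the DEM). A log transform, mean
   normalization and a floor turn this into the rarity index RI: an
   average cell scores exactly 1, no cell scores below the floor (0.05).
5. **Impact metrics.** Per cell,
   `BIM_total = (1 − MSA) · RI · A` and
   `BIM_cocoa = (MSA_nv − MSA) · RI · A` (cocoa cells only), in
   biodiversity-weighted hectares. Yields are downscaled from national
   production by relative suitability, `Y_i = S_i · PD / Σ_j S_j A_j yr`,
   and the biodiversity factor `BF_i = BIM_cocoa,i / (Y_i A_i yr)`
   (ha·yr·t⁻¹) prices a tonne of production in biodiversity terms.
6. **Attribution.** Department-level factors multiply traded tonnages;
   exported volume whose origin is unknown is priced at the average
   factor weighted by each department's untraced volume
   (`max(0, production − traced volume)`), the only mass-consistent
   reconstruction from the available fields.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `msa_lu` | primary forest/vegetation 1.0, lightly used forest 0.7, secondary forest/agroforestry 0.5, low-input agriculture/pasture 0.3, plantation 0.2, built-up 0.05 | – | GLOBIO-class ordering; agroforestry deliberately above low-input agriculture (shade systems retain more intactness) |
| `road_bands` | (500 m, 0.80), (1500 m, 0.90), (5000 m, 0.95) | m, – | disturbance decays with distance; 1 beyond the last band |
| `frag_response` | (1, 0.45) … (10⁴ ha, 1.0), log-linear | ha, – | see numerical choices below |
| `ri_floor` | 0.05 | – | keeps RI positive so impact weights never vanish |
| `flii_threshold` | 6 (0–10 scale) | – | splits lightly-used from secondary forest; no authoritative value exists, so it is config, not a claim |
| `occupation_years` | 1 | yr | one production season links area occupation to annual tonnage |
| `untraced_fraction` | 0.544 | – | share of export volume with unknown origin in the emulated trade structure |

## The synthetic generator: what it does and does not establish

Real inputs for this kind of analysis (national land-cover maps,
remotely-sensed crop maps, IUCN-style range polygons, subnational trade
ledgers) are large and proprietary. The generator builds structurally
faithful stand-ins on one shared grid:

* classes are spatially autocorrelated patches (Gaussian-smoothed noise
  cut at rank quantiles — realized proportions land within a few
  percentage points of targets by construction), not i.i.d. cells,
  because fragmentation responses are meaningless on salt-and-pepper
  noise;
* cocoa only appears on agricultural or forest base cells (encroachment),
  70 % on agriculture; an error is raised if the requested cocoa share
  exceeds the agricultural-plus-forest matrix;
* species ranges are connected blobs with log-normal (right-skewed)
  sizes, so aggregated RWR is right-skewed like real range stacks; by
  default each species' global range equals its in-domain range, making
  per-species RWR mass exactly 1 — a deliberate conservation testing
  hook (`global_inflation` emulates partly-in-country ranges);
* the trade table conserves tonnes exactly and defaults to 54.4 % of
  export volume untraced, drawn proportionally from every department.

A green test on this world establishes the *accounting contracts* of the
method — conservation, partition, monotonicity, convexity of mixing,
counterfactual structure — not the empirical magnitudes of any real
landscape. Classification error, georeferencing noise, and the true
geometry of any country are deliberately not emulated.

## Numerical choices

* **Fragmentation at desk scale.** Published GLOBIO-class fragmentation
  curves saturate near 10⁶ ha. On the ≤ ~2000² grids this package
  targets, every patch would sit on the flat low end and the response
  would collapse to a constant. The shipped default keeps the documented
  shape (non-decreasing, log-linear, saturating at 1) but saturates at
  10⁴ ha so patch size is informative at these extents. Continental runs
  should override `frag_response`.
* **Negative counterfactual losses.** Replacing cocoa by primary forest
  can *lower* total MSA on a cell whose counterfactual forest patch is
  tiny (fragmentation penalty exceeds the land-use gain). Such losses are
  clamped to 0, and the count of clamped cells is logged: the impact
  metric reads loss as damage, not credit. This is also why strict
  per-cell dominance of the counterfactual is only guaranteed with a
  saturated fragmentation table.
* **Log transform of RWR.** "A logarithmic transformation" is undefined
  at RWR = 0, which covers real cells. The default is the unit-free
  `t = ln(1 + rwr/r̄)` with `r̄` the mean positive RWR; a `raw_log`
  variant (zeros floored after normalization) is selectable. Either way
  scores are divided by their mean over all terrestrial cells, so an
  average cell gets exactly 1 before flooring.
* **Road bands.** The multiplier of the first band whose maximum
  distance is ≥ the cell-centre distance applies (closed upper edge);
  built-up cells are exempt since their impact already sits in the
  land-use term.
* **Ties and determinism.** Pasture ties break by row-major cell order;
  overlapping department polygons resolve to the smallest id with a
  warning; cell membership is centre-point containment; one global seed
  fans out to per-stage substreams keyed by stage name, so changing one
  stage's parameters never perturbs another stage's draws.
* **Department factors.** The headline department factor is the plain
  mean of cell BF over the department's cocoa cells (the literal
  "average value"); a production-weighted variant (`bf_weighted =
  BIM_cocoa / production`) is also computed because only under weighting
  is flow attribution exactly mass-consistent — with the cell-mean
  factor the discrepancy is reported, never hidden.

## A worked contract check

```{r example}
g <- grid_spec(64, 64, 100)            # 64 x 64 cells of 1 ha
bundle <- generate_landscape(1, g, n_departments = 6)
cfg <- default_config()
lu <- harmonize(bundle, cfg)
loss <- msa_loss_cocoa(lu, bundle$roads)
ri <- rwr_to_ri(aggregate_rwr(lapply(
  generate_species(1, 30, g, bundle$dem),
  species_rwr, dem = bundle$dem, grid = g)))
y <- downscale_yield(bundle$suitability, lu$cocoa_mask, 1000)
sum(y$values * cell_area_ha(g))        # recovers the 1000 t put in
bc <- bim_cocoa(loss$loss, ri, lu$cocoa_mask, g)
bt <- bim_total(loss$msa$msa_total, ri, g)
c(bim_cocoa = bc$total, bim_total = bt$total, share = bc$total / bt$total)
```

## Known limitations

* No reprojection, tiling, or out-of-core rasters: one in-memory grid.
* MSA responses are taxon-agnostic; hunting and climate pressures are
  absent; the parameter tables are documented package defaults, not a
  calibrated replication of any GLOBIO release.
* Pasture suitability is proxied by livestock density; the pasture/PNV
  split is logged but carries no separate response class.
* Trade emulation splits volumes with a seeded Dirichlet; it reproduces
  mass structure, not trader behaviour.
* The consumption-stage (input–output) extension and ecoregion-scale
  characterization-factor comparisons are out of scope.
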