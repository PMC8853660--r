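---
title: "Mapping functional connectivity between ecosystem-service supplies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping functional connectivity between ecosystem-service supplies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esconnect)
```

## The problem

Ecosystem services (ES) are usually mapped as static supply surfaces, one per
service, with interactions inferred from spatial correlation. That misses the
ecological *processes* that couple services: water regulated by an upland
forest sustains crops and scenic river valleys far downslope; a wetland both
regulates flow and is itself scenic. `esconnect` treats the high-value supply
areas of several ES as nodes of a connectivity network and draws *directed,
mechanism-specific links* between them, either where supplies co-occur in the
same cells (overlap links) or where downslope surface waterflow carries the
influence of one supply area to another (topographic links). The package
covers three services: plant-food agriculture (PA, provisioning), waterflow
regulation (WF, regulating) and landscape aesthetics (LA, cultural).

Everything operates on co-registered rasters in a projected metric CRS
(roughly 29 m cells in the motivating regional data). Cells are addressed by
`(row, col)` with row 1 on top; a cell belongs to a zone iff its *centre*
lies in the zone — there is no partial-cell area weighting, so all areas are
exact cell-count arithmetic (`ha = cells x cellsize^2 / 10^4`). Nodata cells
never enter sums, thresholds or components.

## Supply areas

For each ES, `top_value_mask()` keeps the top-valued fraction (default 50%)
of *supply-positive* cells: the threshold is the `(1 - top_fraction)`
quantile of the positive unmasked values, and cells tying the threshold are
retained, so an all-equal raster keeps everything. The exact reading of a
"top-50%" rule is genuinely open — by cell-value quantile or by cumulative
value share — so both are implemented (`threshold_mode`); the quantile
reading is the default because it is scale-free and reproduces the
half-the-cells intuition.

`delineate_supply_areas()` then aggregates retained cells into areas:

* **WF and LA**: connected components of the mask. Adjacency defaults to
  queen (8-neighbour) as the most permissive reading of "immediately
  adjacent"; rook is available.
* **PA**: farmland comes as a parcel fabric, so parcels are first dissolved
  (`dissolve_parcels()`: touching parcels merge, crop attributes
  concatenate) and each dissolved parcel clipped to the mask. This respects
  the fact that a farm is a management unit, not a pixel cluster.

Raw area values follow service-specific logic: PA = potential crop area
(ha); WF = summed WF model value over the area; LA = area (ha) x LA model
value. For LA the "model value" of a multi-cell area is taken as the *mean*
cell value — multiplying area by a summed value would count area twice — with
a config switch for the sum reading. Raw values are min-max normalized per
ES onto the unit-less 1–10,000 scale (`normalize_weights()`); a degenerate
group (all equal) maps to 10,000, treating every member as top-ranked.
Normalization is per-ES because the three services are valued in different
natural units.

## The eight link types

`link_rules()` registers the complete set of mechanisms; no other ordered
pair can be instantiated, which a test enforces:

| direction | class | weight rule |
|---|---|---|
| WF → PA | overlap | summed WF *supply-area* values within the PA area |
| PA → WF | overlap | all summed WF values within the *entire* PA area |
| LA → WF | overlap | summed WF values within the LA area |
| WF → LA | overlap | summed WF *supply-area* values within the LA area |
| PA → LA | overlap | summed LA values within the PA area |
| WF → WF | topographic | summed WF values along the corridor |
| WF → PA | topographic | summed WF values along the corridor |
| WF → LA | topographic | summed WF values along the corridor |

The wording difference between "supply-area values" and "entire area" is
treated as intentional and becomes two zonal scopes: intersection-restricted
sums run over the pair intersection (necessarily inside top-value source
cells), entire-area sums run over every cell of the source polygon whether
or not the weighting raster is top-valued there. Both reduce to
`zonal_sum()`, and the tests verify every weight against brute-force
per-cell loops.

Overlap links are a directed GIS clip: each source/recipient pair with a
non-empty cell intersection yields links, one per single-part
(queen-connected) intersection polygon by default — the census convention —
with `split_parts = FALSE` keeping one multi-part link per pair. Links whose
intersection is entirely nodata in the weighting raster are kept with weight
0 and flagged. Link weights are normalized to 1–10,000 *within each rule
group*, again because rules weigh in different units.

## Topographic corridors

Topographic links always originate at WF supply areas and represent
downslope surface waterflow. The chain is:

1. **`fill_depressions()`** — priority-flood filling; the filled DEM is
   `>=` the input everywhere and every cell gains a non-ascending exit path.
   An epsilon variant (`eps = 1e-6` m) imposes a tiny gradient across filled
   flats so steepest-descent routing stays defined; routing always runs on
   the epsilon-filled surface.
2. **`build_resistance()`** — directed move costs on the 8-connected cell
   graph, diagonals distance-corrected by sqrt(2). Every strategy charges at
   least `dist x (1 + k x climb)` (default k = 1 per metre: climbing 1 m
   costs like a 29 m detour at 29 m cells). The default `"downslope"`
   strategy additionally multiplies cost by `1 + c_low x deficit`, where
   `deficit` is the descent gradient (m/m) the move forgoes relative to the
   cell's steepest descent. Under this cost the D8 steepest-descent receiver
   tree is exactly the zero-penalty graph, so least-cost routes track the
   drainage network — which is the property that justifies using LCP
   corridors as waterflow proxies at all. `c_low = 500` makes a 0.1 m/m
   deficit cost ~50x distance, enough that corridors deviate from drainage
   only where drainage cannot reach the goal; `lcp_d8_agreement()` measures
   ~99% mean cell agreement over random synthetic terrains and exact
   agreement on a noise-free cone. Two alternative strategies are kept for
   comparison (`"climb"`, uphill-penalty only, whose corridors shortcut
   across hillslopes at ~25% drainage agreement, and `"lowground"`,
   ~70%), because the "right" elevation-based conductance is a genuine
   modelling choice and the drainage-agreement gate is the criterion we
   chose to decide it.
3. **`lcp_path()`** — deterministic Dijkstra (ties broken by smallest
   predecessor index, so runs are exactly reproducible).
4. **`make_subbasins()`** — D8 watershed labelling: every cell is labelled
   by the terminal its receiver chain reaches, either a natural terminal
   (valley mouth at the grid edge) or a supplied interior pour point.
   Basins partition the landscape; each basin's outlet is its lowest edge
   cell.
5. **`trace_wf_corridors()`** — one LCP per WF area from its
   lowest-elevation cell (water leaves an area at its low point; the paper
   leaves the start convention open, and a config alternative snaps to the
   centroid) to the outlet of the sub-basin containing that start cell.
   Areas straddling a divide are assigned by the start cell with a warning.
6. **`attach_ilf()`** — influential landscape features (wetlands,
   floodplains, riparian areas, seasonally flooded fields) downstream of a
   basin extend its corridors: one outlet-to-ILF least-cost extension per
   (basin, zone), computed once and appended to every member corridor, with
   additive cost. Untagged zones are tagged automatically by following the
   D8 chain from each outlet.
7. **`segment_paths()`** — corridors are cut into source → recipient links:
   each recipient area the corridor enters yields one link whose geometry is
   the sub-path from the source's exit cell to the recipient's first entered
   cell. Cells inside the source area are excluded from geometry and weight
   by default (the corridor is the *between*, not the source itself; a flag
   includes them). WF → WF links form only between spatially isolated pairs,
   implemented as not queen-adjacent; WF → PA recipients must lie in the
   corridor's own sub-basin or inside an ILF zone, reflecting where farms
   can plausibly receive the regulated flow.

Corridor geometry is the one-cell-wide traced path; weights are summed WF
values over the traced cells, each cell once.

## Amalgamation and LULC coverage

`amalgamate_links()` accumulates, per cell, the weight of every link
covering it (overlap polygons by member cells, corridors by traced cells).
The default accumulates the per-rule *normalized* weights so that no link
type dominates by unit scale — summing raw weights would let the largest
natural unit swamp the map — and a switch accumulates raw weights for users
who want physical units. Accumulation is order-independent.

`lulc_coverage()` compares the union footprint of any feature set against a
categorical land-cover raster: covered ha, share of the feature union, and
share of the class total. Overlay classes (parkland lying over forest,
grassland, shrub or rock) are computed from independent masks, so summed
percentages can legitimately exceed 100. Features of one class are unioned
first — overlapping links never double-count coverage area, although they do
sum in the amalgam raster.

## The synthetic landscape

`simulate_bundle()` generates, from one seed, the full input bundle every
test and the acceptance script run on: DEM, sub-basins, LULC with a park
overlay, PA/WF/LA rasters, a parcel fabric and ILF zones. It emulates the
*structure* the pipeline assumes, at desk scale (default 120 x 120 cells of
29 m, ~12 km2):

* **Terrain**: valley-floor gradient descending to boundary exits, hillslope
  gradient away from a dendritic valley network (two valleys with one branch
  each by default), a boundary rim faded at the exits, plus smooth Gaussian
  noise (sd 1.5 m against per-cell slopes of several metres, so depressions
  are rare: the fill changes well under 5% of cells). Interior pour points
  at ~55% of each stream split every valley into an upper sub-basin and a
  lower one holding ILF zones — so downstream ILF merging is always
  exercised.
* **LULC**: a mid-valley lake (the only mapped waterbody — small streams are
  sub-cell at 29 m), wetland strips flanking the stream, floodplain
  agriculture in the lower reaches, and elevation-zoned upland classes at
  quantile targets (forest dominant, rock on top), with a circular park
  overlay spanning several upland classes.
* **WF**: LULC-perviousness weights times smooth noise on every terrestrial
  cell, scaled so that after multiplying ILF patches by 3 all values lie in
  19–1200, the range of the regional waterflow-infiltration modelling the
  magnitudes are borrowed from; zero on waterbodies.
* **PA**: positive only on farmland, higher on low floodplain ground,
  organized as a fabric of adjacent parcel blocks so dissolving has work to
  do. Seasonally flooded fields near the stream are ILF patches, which is
  what makes farm cells reach the top-WF mask and gives the PA/WF overlap
  links their mechanism.
* **LA**: a per-class value table (water highest, wetland and forest high,
  urban lowest, park bonus), scenic vineyard parcels, plus smooth noise —
  broad and positive across terrestrial and aquatic cells.

The generator reproduces bit-identically per seed and guarantees at least
one link of every one of the eight types on the default bundle. What it does
*not* emulate: real hydrography (braided channels, lakes chains), the
empirical value distributions of any particular region, registration error
or nodata holes, and supply surfaces at the tens-of-millions-of-cells scale
of a real regional analysis. Green tests therefore certify the mechanics of
delineation, weighting, routing and accounting — not the ecological validity
of any particular regional map.

## Numerical choices and degenerate inputs

* Deterministic everywhere: Dijkstra ties by smallest predecessor index,
  component labels in row-major first-cell order, D8 ties by a fixed
  neighbour order (cardinals before diagonals), one seed for the generator.
* Zero-length corridors (a WF area containing its own outlet) are legal and
  weigh 0; all-zero supply rasters yield an empty mask with a warning;
  all-nodata intersections keep their link, flagged, at weight 0;
  single-element normalization groups map to 10,000.
* Rasters are exchanged as ESRI ASCII grids with full double precision
  (exact round trips) plus `.prj` sidecars; geographic-CRS inputs are
  rejected with advice to reproject. Vectors travel as GeoJSON.
  `dissolve_parcels()` is exact cell-set algebra when a grid is supplied
  (always true in the pipeline); the gridless fallback uses a shared-vertex
  test that is exact for boundary-sharing parcel fabrics only.

## Problem sizes

The test suite runs landscapes from 1 x 12 strips (hand-enumerable
segmentation) through 120 x 120 default bundles; drainage validation uses
50 seeded 100 x 100 terrains with 10 traces each, and the full suite
completes in well under a minute. These sizes were chosen so every expected
value in a test is either hand-computable or reproducible by an independent
brute-force oracle; the pipeline itself is linear in cells plus
O(corridors x Dijkstra) and runs a 200 x 200 bundle in seconds.

## Known limitations

* Only synergistic mechanisms are represented; no trade-off (negative)
  weights.
* The eight-rule registry is closed by design; adding services means adding
  mechanisms, not reusing these.
* Corridor weighting uses the one-cell path; buffered corridors are a
  display option, never a weighting one.
* LCP is the only corridor model: no circuit theory, graph centrality or
  network flow.
* The overlap census depends on the single-part convention; the multi-part
  counter is provided but not the default.
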