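---
title: "Methods: building and validating human footprint maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating human footprint maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The human footprint (HF) index condenses mapped human pressures — built
environments, agricultural land use, population, roads and railways,
electrical infrastructure, oil and gas, mining, and an accessibility-based
indirect pressure — into a single per-pixel score of how far a landscape has
moved from its natural state. `footprintr` implements the full national-scale
workflow at 30 m resolution: score each input dataset, combine datasets into
pressure layers, aggregate pressures into the index, mask water, and validate
the result against plot-level interpretation scores. This vignette explains
the model choices, the tunable parameters, and what the synthetic-landscape
tests do and do not establish.

## The scoring template

Every dataset is graded against four impact criteria, in decreasing
importance: loss of original cover (weight 4), surface imperviousness (3),
habitat viability/passage (2), and pollution risk (1). The weights sum
to 10, so the importance-weighted sum of a dataset's qualifications — each
in [0, 1] — is its *maximum score*, never exceeding 10. A score of 4 or more
marks loss of the original ecosystem. `hf_score_table()` reproduces the
seventeen reference dataset rows by computing, not storing, the weighted
sums; `dataset_max_score()` exposes the same arithmetic for new datasets.

Six scoring cases turn prepared layers into scored rasters in [0, 10]:

* **Direct lookup** (`score_direct()`, and `rasterize()` for vector
  features): categorical layers and linear features carry their score at
  the mapped location. Shipped defaults: urban 10, runways 8.75,
  settlements/sparse houses 7.5, pasture 5.5 (Peru) / unified 5.25
  (Ecuador-style), agriculture 5.25, plantations 4.5, primary
  roads/railways 8.75, secondary 8.25, country roads 6, trails 1.25,
  pipelines 5.25, transmission lines 5.
* **Exponential distance decay** (`score_exponential_decay()`): influence
  is strongest at the source and fades over a finite horizon. The paper
  series states only "decays exponentially" with an origin score and a
  maximum distance, so the functional form here is
  `s(d) = S0 exp(-d ln(S0/floor)/D)`, which passes exactly through `S0` at
  the source and a configurable `floor` (default 0.1) at the horizon `D`,
  and is cut to 0 beyond. The floor is the one free parameter this choice
  introduces; it is exposed everywhere it is used.
* **Logarithmic count scoring** (`score_log_count()`): population counts
  score `5.41 log10(count + 1)`, saturating at 10 above 70 persons per
  pixel. The logarithm must be base 10: with a natural log the stated
  coefficient would put 70 persons near score 23, contradicting the
  intent that the threshold sits near 10 (base 10 gives 10.015, capped).
* **Logarithmic density scoring** (`score_log_density()`):
  `2.5 log10(density + 1)`, for census-derived densities.
* **Linear scoring** (`score_linear()`): nighttime-light radiance maps
  linearly from the 0.5 noise floor to the 60-unit urban ceiling onto
  [0, 10]; gas flares and the brightest city cores sit above 60 and
  saturate.
* **Point scoring** (`score_points()`): points at *actual* locations burn
  their score on all pixels whose centers fall within a feature-size
  radius (wells 50 m, filling stations 150 m, refineries/deposits 500 m,
  electrical points 50 m, mines 50 m); points at *approximate* locations
  (settlements, ports) score only their own pixel and radiate a decay
  halo from 4 down to the floor at 100 m.

Every case caps its output at the dataset maximum, and scored values of a
nodata input stay nodata.

## Indirect pressure from accessibility

Pressures that accompany human presence without being mapped — hunting,
selective logging, firewood collection — are modelled through travel time
from inhabited places. A speed surface assigns every pixel the first
matching rule in strict precedence: roads (primary 60, secondary 40,
tertiary 30 km/h), coastline navigation (20), waterway navigation (a 5 × 5
matrix over slope bands <5/5–10/10–15/15–25/>25 % and elevation bands
<450/450–700/700–1800/1800–2800/>2800 m), walking across agricultural land
(`10.560326 · slope^-0.199553`), and walking through natural vegetation
(`-0.975931 · ln(slope) + 6.761258`, halved when flooded). Water pixels
not on a navigable line are barriers.

Two numerical guards are needed where the paper's formulas are silent:
both walking laws diverge (or become meaningless) as slope → 0, so slope
is clamped to ≥ 1 % before evaluation; and the natural-vegetation law goes
negative on extreme slopes, so walking speed is floored at 0.1 km/h. Both
constants are `speed_model()` parameters.

Crossing a 30 m pixel horizontally or vertically takes
`0.03 km / v(km/h)` hours; movement is 4-connected to match that
definition, and a step between adjacent pixels costs the mean of their
crossing times — the standard accumulated-cost convention. Sources are
8-connected clusters of at least two built-environment pixels (isolated
single pixels are treated as mapping noise, not habitation); "built
environments have speed 0" is read as *zero traversal cost*, since
literally 0 km/h would make the sources impassable, so the cost raster is
zeroed on the source mask and the multi-source Dijkstra solver (compiled
code under `src/`) starts them at time 0. Travel times are scored with
the same decay form as above, from 4 at the sources to the floor at the
4-hour horizon — a routine daily travel budget — and 0 beyond; pixels cut
off by barriers score 0 rather than nodata, expressing "no routine human
influence" rather than "unknown".

Country-scale runs that exceed memory can be tiled
(`tiled_least_cost()`): travel time is computed per overlapping tile and
mosaicked by pixelwise minimum. With overlap spanning the grid this is
exactly the untiled result; with less overlap it can only overestimate,
and the suite verifies both properties.

## Assembly

Scored datasets of one pressure combine by pixelwise maximum (the
strongest mapped influence wins; a road crossing a scored LULC pixel does
not double count). Pressure layers then aggregate by pixelwise **sum**
into the index — the additive convention of the global-HF lineage; the
source series says "aggregated" without a formula, and the sum is what
makes its 0–30 presentation scale attainable with eight pressures capped
at 10. Water is masked to nodata and the result is rounded half-even to
two decimals, once, at the end. `classify_hf()` provides the generic
landscape reading with breaks at 1, 4 and 15.

Input-selection strategies are dataset filters, not separate pipelines:
"SDG15" (non-restrictive) uses everything, "Official" keeps nationally
produced datasets, "Multitemporal" keeps per-year datasets. A provenance
table (dataset, pressure, case, parameters, flags, year) is attached to
every built map.

## Validation protocol

The technical validation compares the map against an independent
plot-level index. A reference human-influence raster is stratified at
4/8/18 into very-low/low/medium/high strata (the printed bound for the
top stratum contradicts the medium stratum's upper bound; it is read as
≥ 18). Sample counts follow a compromise allocation: proportional to
stratum area, then every stratum raised to a floor paid for by the
largest strata, keeping the total fixed. Plots are 300 m squares drawn
uniformly without replacement within strata, with 5 km context buffers
for indirect presence; the total sample size is a configuration input
(the national series derived theirs from an expected overall error of
0.0015, a derivation not reproduced here).

Interpreter scores are banded — area pressures 0–3 by coverage (0 %,
≤12 %, 13–50 %, >50 %), line/point pressures 0–3 by occurrences, indirect
pressure a presence flag worth a fixed standardized value of 2. Scores
standardize to each pressure's maximum (`(score/3) · max`), combine by
maximum within a pressure, sum across pressures, and normalize by the sum
of per-pressure maxima to land in [0, 1]. The map-side index at a plot is
assembled the same way from the per-pressure layer values, which differs
from reading the rounded HF map only by the final 2-decimal rounding and
keeps the two sides of the comparison structurally identical.

Agreement metrics: a tolerance kappa (two normalized scores agree when
they differ by less than 0.20; chance agreement is the agreement rate
over all ordered cross-pairs, which avoids binning continuous scores),
RMSE, and R² as the squared Pearson correlation. With both indices on the
unit scale an RMSE of 0.1 reads as "off by roughly 10 %".

## The synthetic landscape

`generate_landscape()` produces a seeded, fully self-consistent input
bundle on a 500 × 500 grid at 30 m (a 15 km desk-scale country; all
problem sizes in the suite — 20 × 20 oracle grids, 200 × 200 tiling
checks, 500 × 500 end-to-end runs — were chosen as the smallest sizes at
which each property is meaningfully exercised). Terrain is smoothed
Gaussian noise scaled to a 3 500 m relief, with slope in percent by
central differences. LULC assigns eight classes (forest, flooded forest,
shrub, water, agriculture, pasture, plantation, urban) by rank
thresholds on two smoothed fields — one separating human-use from natural
land, one ordering classes within each side — so requested class
fractions are hit essentially exactly. Settlements derive from urban
cluster centroids plus clustered satellites; a spanning tree over them,
classed by edge length, gives the hierarchical road network; trails,
a railway, steepest-descent waterways and an optional coastline complete
the networks. Population is log-normal noise over a blurred
urban/settlement kernel scaled to a 150-person maximum (so the 70-person
cap is exercised); radiance is blurred population rescaled to 55 with
80-unit flares at the first wells (so the 60-unit linear ceiling is
exercised). Default fractions (40 % forest, 15 % agriculture, 10 %
pasture, 6 % urban, 5 % each water/flooded forest/plantation, 14 % shrub)
describe a plausible piedmont mosaic and are ordinary parameters.

`generate_visual_truth()` stands in for the human interpreter. In its
default exact mode it emits continuous 0–3 scores that invert the
standardization, so a noiseless run must return kappa = 1, RMSE = 0,
R² = 1 — a full-protocol parameter-recovery check. The banded mode
(`quantize = TRUE`) pushes true coverage through the interpreter bands
and collapses indirect pressure to presence, emulating the information
loss of real visual scoring; the two modes are kept separate because
banded scores cannot reproduce the continuous index exactly, and
conflating quantization with interpreter noise would hide which one
degrades the metrics. Gaussian noise on the 0–3 scale models interpreter
error; the suite checks that RMSE rises and kappa falls monotonically in
the noise level, averaged over seeds.

What passing these tests shows: the scoring arithmetic, the accessibility
solver (against an independent graph-library oracle), the assembly
algebra, and the validation statistics are internally correct and the
whole chain is self-consistent. What they do not show: anything about
real input data — registration errors, attribute noise, OSM completeness,
census displacement, cloud contamination — or about the ecological
validity of the scores themselves.

## Known limitations

The accessibility model ignores slope direction, seasonality, transport
preferences and mode-transfer times. Rasterization is all-touched for
lines and center-containment for single-ring polygons (no holes or
multipart rings). Reprojection is an input-preparation contract: layers
must already share the grid CRS, and `resample()` only changes grid
geometry within one CRS. File exchange uses plain-text formats (ESRI
ASCII grids and vertex CSV tables); the in-memory raster container is a
plain matrix bound to a grid contract, sized for national tiles rather
than continental mosaics.
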