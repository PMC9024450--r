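---
title: "County-level grain yield-gap analysis: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{County-level grain yield-gap analysis: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldgapr)
```

`yieldgapr` analyses the gap between what county farmland could yield under
its natural restrictions and what it actually yields, how that gap moves
across decades, where it clusters in space, which of 27 candidate factors
drive its change, and which counties offer the most improvement capacity.
This vignette is the package's own account of the science: the models, the
parameters that matter, the choices that were genuinely open, and what the
synthetic test bed does and does not demonstrate.

## The step-wise potential-yield model

Potential yield is estimated per raster cell by successively revising the
photosynthetic production potential for temperature, water and soil
restrictions, in the agro-ecological-zone tradition:

$$YQ = 10^5 \frac{Q}{C}\, F\, E, \qquad
  YT = \frac{T}{30}\, YQ, \qquad
  YW = f(w)\, YT, \qquad
  YS = f(s)\, YW$$

* `Q` — growing-season (May–October) **total solar radiation**, kcal cm⁻².
  Dividing by the calorific value of dry matter `C` (default 4.25 kcal g⁻¹)
  converts energy to grams of dry matter per cm²; the factor $10^5$
  converts g cm⁻² to kg ha⁻¹.
* `F` — light-energy utilization rate, default 0.03.
* `E` — economic coefficient, the harvestable fraction of dry matter.
  Grain crops sit between 0.35 and 0.5; the default 0.4 suits
  rice-dominated double-cropping systems.
* `T` — growing-season **mean temperature**, °C, scaled against a 30 °C
  reference. The temporal statistic (total for Q, mean for T) is a
  documented convention, configurable in principle but fixed per run.
* `f(w)` — water correction in [0, 1]; 1 where rainfall exceeds
  evapotranspiration (the default, appropriate for humid rice regions).
* `f(s)` — soil correction in (0, 1], supplied as a raster layer built
  elsewhere from elevation, pH, fertility, slope and texture; only the
  multiplication is in scope here.

Two design points deserve emphasis. First, the `T/30` ratio is **clamped
to [0, 1]** by default: the source formulation never addresses
temperatures above 30 °C or below 0 °C, and clamping is the only choice
that preserves both the "potential" semantics and the monotone chain
`YQ ≥ YT ≥ YW ≥ YS` on every cell. The unclamped mode remains available
(`clamp_temperature_ratio = FALSE`) for sensitivity runs and is recorded in
the fitted grid's parameters. Second, every step is linear in its input,
so scaling `Q` by `k` scales all downstream surfaces by `k` — a property
the tests exploit.

Internally all potentials are kg ha⁻¹; conversion to t ha⁻¹ happens once,
at county aggregation, to avoid repeated rounding. Aggregation is a
**center-point zonal mean over cultivated cells only** (paddy or dryland
classes): a cell belongs to the county containing its center, the simplest
deterministic rule. Counties with no cultivated cell are reported missing,
never zero. The evaluation resolution is a configuration knob, not a model
constant: the sources of real inputs differ in native resolution and no
single correct value exists.

## Gap statistics

Per county and epoch, with `ȲS` the mean potential and `ȲFARM` the mean
actual farm yield (t ha⁻¹):

$$YGAP = \bar{Y}_S - \bar{Y}_{FARM}, \qquad
  RYGAP = 100\,\frac{YGAP}{\bar{Y}_S}, \qquad
  YGC_{i} = YGAP_{i,t+1} - YGAP_{i,t}$$

Negative `YGC` means the gap is closing. Sub-period changes telescope
exactly to the full-period change, an identity asserted per county on
every fixture.

Report-style binning uses edges `<3, 3–6, 6–9, 9–12, ≥12` t ha⁻¹. Printed
tables of this kind do not state boundary ownership, so the package fixes
the deterministic convention **half-open `[lo, hi)`** — a value of exactly
6 t ha⁻¹ falls in `6–9`. Bin ratios are percentages of the non-missing
county total, rounded to two decimals only in report output; machine
outputs keep full precision. A county whose farm yield exceeds its modeled
potential gets a negative gap that is **flagged, not clipped** — hiding a
model/data inconsistency would be worse than seeing it.

## Spatial clustering

Weights are **queen contiguity, row-standardized** by default. The choice
was open — the analysis tradition names the statistics but rarely the
weights — and queen is the common default for irregular county lattices;
rook is exposed alongside. Contiguity is derived by shared-vertex matching
on a snap grid (rook requires a shared edge, i.e. at least two shared
boundary vertices), which is exact for tessellations whose boundaries
share vertices; isolates abort the run unless explicitly allowed.

Hot spots use the **self-inclusive Getis–Ord Gi*** on binary neighborhoods
(the form that "hot-spot analysis" denotes in GIS practice; plain Gi is a
flag away), with hot/cold classes at |z| thresholds 1.65/1.96/2.58. When a
county's neighborhood spans the entire map the statistic's numerator is
identically zero and its variance term vanishes; the package defines the
z-value as 0 there.

The relation between gap changes of successive periods uses **bivariate
Moran's I**, $I_{xy} = \sum_{ij} w_{ij} z_{x,i} z_{y,j} / S_0$, the
correlation of one variable with the spatial lag of another, plus its
local (LISA) decomposition $I_i = z_{x,i} \sum_j w_{ij} z_{y,j}$.
Standardization uses the population (n-denominator) standard deviation,
matching the classical derivations. Inference is by **conditional
permutation** — `y` shuffled across locations with `x` fixed; locally, the
rest of the map is drawn into each county's neighborhood — with the
`(exceed + 1)/(n_perm + 1)` pseudo p-value, 999 permutations and a
mandatory seed. LISA classes come from the sign quadrant of
$(z_{x,i}, \mathrm{lag}_i)$, gated at `alpha = 0.05`. No multiple-testing
correction is applied by default, mirroring common practice in this
literature; the permutation machinery makes adding one straightforward.

## Determinant ranking

Yield-gap change per period is regressed on the 27 candidate factors — 4
climatic, 7 socioeconomic, 7 land-use, 9 human-investment — with a random
forest, after dropping municipal districts (agriculture is not their main
industry) and counties with any missing determinant in that period; on the
default synthetic region this leaves 94 of 121 counties, emulating the
~95-of-122 retention of a real provincial panel. Fewer than 20 retained
counties aborts the fit.

Open choices, fixed as package defaults and logged with every run:
**permutation (out-of-bag) importance** rather than impurity importance,
because the latter is biased toward high-cardinality variables; 1000
trees; all features considered at each split (`mtry = p`), which sharpens
the separation of planted signal from noise at n ≈ 95. Raw importances
are floored at zero and divided by their maximum, the only simple map that
guarantees scores in [0, 1] with the top factor at exactly 1. Ties at the
top-10 boundary break deterministically by factor name and are logged.
Key-factor "contribution" per category is simply the share of top-10
slots, so the four categories always sum to 100%.

## Screening and the uplift scenario

Since roughly 15–25% of a yield gap is considered unexploitable, counties
are screened at a **relative gap strictly greater than 30%** in the final
epoch; boundary counties at exactly 30% are excluded and logged. Municipal
districts are removed from the selection. The incremental-production
scenario applies a 5% uplift to the **actual** farm yields of the selected
counties: `sum(sown_area × actual_yield × uplift)` tonnes — linear in the
uplift and additive over counties by construction.

## The synthetic study region

The generator is first-class, tested code: it defines the conditions under
which every end-to-end property is asserted.

* **Counties** — an 11×11 contiguous lattice (121 units, close to a
  province's ~122), each 8×8 cells of 1 km; a central 5×5 block is flagged
  municipal-district to exercise the exclusion rule.
* **Climate** — Gaussian-smoothed white noise rescaled into ranges,
  giving distance-decay autocorrelation with no heavy dependencies
  (spectral synthesis would add machinery without changing what the tests
  can show). Defaults: Q ∈ [95, 120] kcal cm⁻², T ∈ [24, 28] °C. With the
  soil field centred on 0.42 these put the region-mean YS near 11 t ha⁻¹,
  inside the 10–14 t ha⁻¹ band reported as plausible for double-cropping
  systems in comparable regions — the justification for the ranges.
* **Soil** — static smoothed field, mean 0.42, half-spread 0.08, clipped
  to (0, 1]. **Water** — f(w) = 1 everywhere.
* **Land use** — a static cultivated mosaic (cultivated probability
  0.45–0.75, paddy share 0.55–0.80 of cultivated cells).
* **Farm yields** — per epoch, an exploitation fraction
  `base(epoch) + Σ effect × standardized covariate + noise`, clipped to
  [0.05, 0.95], multiplies the county mean YS. The default schedule
  (0.37, 0.55, 0.57, 0.51) reproduces the qualitative historical pattern:
  strong gap narrowing in the first decade, partial widening later, with
  relative gaps moving from ~63% to ~49%.
* **Determinant panel** — pragmatic county-scale marginals with a shared
  latent factor (mild cross-correlation), multiplicative epoch trends
  (economic growth, declining farm labor), static terrain, and two
  non-district counties with a missing quality level in every epoch.
  Planted effects default to GDPPC (0.08), SH (0.04), PCAI (0.02) on the
  exploitation scale.

Everything derives from one seed through fixed offsets, so a fixture set
is byte-identical across runs — the basis of the end-to-end determinism
test.

For parameter recovery the package also ships a direct design,
`simulate_factor_response()`: 27 independent standardized covariates,
planted coefficients β = (1.0, 0.5, 0.25) on three of them, noise sd 0.5,
n = 95. This isolates the importance model from the pipeline: in the full
landscape the same covariate raises exploitation in *both* epochs of a
period, so much of its effect cancels in the gap change — a realistic
feature, but one that would conflate generator design with estimator
quality in a recovery test.

What the generator does **not** emulate: real climatology or station
interpolation, the full land-use legend of real products, realistic
covariate marginals, or measurement error in yearbook yields. Passing
tests therefore demonstrate correctness of the computations and
recoverability under known structure — not that any particular real
region's numbers would be reproduced.

## Numerical choices and degenerate inputs

* Zero-variance inputs error loudly everywhere a standardization occurs.
* Degenerate climate ranges (min = max) yield constant fields; a
  temperature range touching 0 °C is rejected at configuration time.
* Raster nodata is `NA` internally and excluded from every aggregation;
  ASCII-grid round trips print 17 significant digits so doubles survive
  exactly.
* All report rounding (2 decimals) happens at the report boundary only.
* Permutation counts below 99 are rejected; pseudo p-values can never be 0.
* Sub-seed derivation keeps every stage independently reproducible and
  inside 32-bit integer range.

## Problem sizes used by the test suite

The suite exercises the defaults end to end: 121 counties × 4 epochs,
999 permutations, 1000 trees, run twice for the byte-identity check;
permutation-test calibration uses 500 replicates on a 49-county lattice;
importance recovery uses 100 seeded replicates at n = 95. These sizes are
the package's chosen balance between statistical resolution (Monte-Carlo
standard errors small enough for ±2-SE bands to be meaningful) and a test
suite that stays pleasant to run.

## Known limitations

* The soil coefficient is consumed, not constructed; its provenance is
  the user's responsibility.
* A single season-aggregate surface is computed; early/late crop splits
  within the double-cropping season are not modelled separately.
* One projected CRS per run; inputs in other CRSs are rejected rather
  than silently reprojected, and no resampling toolchain is provided.
* Importance ranking is associational; no spatiotemporal mechanism or
  causal claim is implied.
* Rook contiguity by shared-vertex matching assumes boundary vertices are
  shared between neighbors, as in lattices and typical cadastres;
  unaligned polygon borders would need a geometry engine.
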