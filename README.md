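# yieldgapr

County-level grain **yield-gap analysis** for agroecologists and land-use
researchers: how far actual farm yields sit below the yield the local
light, temperature, water and soil conditions would allow; how that gap
has moved across decades; where gaps and gap changes cluster in space;
which of 27 candidate factors drive the change; and which counties offer
the most capacity for yield improvement.

The analysis chain mirrors the practice of provincial yield-gap studies in
double-cropping grain regions, but runs entirely on a seeded synthetic
county landscape with known ground truth, so every stage is testable
without proprietary rasters or statistical yearbooks.

## The model

Potential yield is estimated per raster cell by step-wise revision of the
photosynthetic production potential (kg ha⁻¹):

```
YQ = 1e5 * Q / C * F * E      photosynthetic potential
YT = (T / 30) * YQ            light-temperature revision (ratio clamped to [0, 1])
YW = f(w) * YT                water revision,  f(w) in [0, 1]
YS = f(s) * YW                soil revision,   f(s) in (0, 1]
```

with `Q` the growing-season total solar radiation (kcal cm⁻²), `C` = 4.25
kcal g⁻¹ the calorific value of dry matter, `F` = 0.03 the light-energy
utilization rate, `E` = 0.4 the economic (harvestable) coefficient and `T`
the growing-season mean temperature (°C). County statistics then follow:

```
YGAP  = mean(YS) - mean(YFARM)        yield gap, t/ha
RYGAP = 100 * YGAP / mean(YS)         relative yield gap, %
YGC   = YGAP(t+1) - YGAP(t)           yield-gap change (negative = closing)
```

Spatial structure is assessed with self-inclusive Getis–Ord Gi\* hot-spot
classes and bivariate Moran's I / LISA (the correlation of one period's
gap change with the spatial lag of the next), under conditional
permutation inference. Determinants of `YGC` are ranked by seeded
random-forest permutation importance, normalized to [0, 1]; counties with
`RYGAP > 30%` (municipal districts excluded) form the improvement set,
and a 5% uplift of their actual yields gives the incremental-production
scenario.

## Worked example

```r
library(yieldgapr)

region <- simulate_region(sim_config(seed = 7))
region
#> <synthetic_region> 121 counties, 4 epochs, seed 7
#>   mean YS by epoch (t/ha): 11.26, 11.39, 11.40, 11.79

yt <- county_yield_table(region$ys_table, region$panel)
subset(gap_summary(yt), epoch == "E1990")[, c("epoch", "mean", "bin", "n", "ratio")]
#>   epoch     mean  bin  n ratio
#> 1 E1990 7.066311   <3  0  0.00
#> 2 E1990 7.066311  3-6 28 23.14
#> 3 E1990 7.066311  6-9 82 67.77
#> 4 E1990 7.066311 9-12 11  9.09
#> 5 E1990 7.066311 >=12  0  0.00

res <- run_pipeline(sim_config(seed = 7), outdir = "demo_run")
res$bimoran[[1]]
#> <bivariate_moran> I = -0.2525, pseudo-p = 0.001 (999 permutations)
nrow(res$selected); res$incremental_tonnes
#> [1] 94
#> [1] 56142.53
```

Reading: the synthetic province's mean potential sits near 11.3 t/ha and
its first-epoch mean gap at 7.07 t/ha (most counties in the 6–9 t/ha
bin). Gap changes of successive periods are weakly negatively
autocorrelated in space (I = −0.25, significant at the permutation
pseudo-p), 94 of the 121 counties clear the 30% relative-gap screen after
excluding the 25 municipal districts, and lifting their actual yields by
5% would add ≈56,000 t of grain. `run_pipeline()` writes every stage's
CSV (county potentials, yield table, gap changes, hot spots, LISA,
importances, screening) plus a config snapshot to the run directory, and
is byte-identical across runs with the same seed.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/yieldgap.R --seed 7 --outdir demo_run --n-perm 999
```

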