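# gravityflow

Gravity-model analysis of settlement-level internal migration.

National census series record how many people live in each settlement at
each wave, but not who moved where in between. **gravityflow** is for
spatial demographers and mobility modellers who want to reconstruct and
analyse those hidden origin–destination flows over long census series: it
predicts flows with an unconstrained (total-constrained) spatial
interaction model, calibrates the model against intercensal population
change, validates it at settlement and regional scale, and quantifies how
terrain ruggedness structures net migration. A synthetic settlement-system
generator with known ground truth makes the entire pipeline testable end
to end.

## The model

Flows between settlements $i \ne j$ follow the gravity form

$$F_{ij} = k \, P_i \, P_j^{\gamma} \, f(d_{ij}),$$

with origin population $P_i$, destination attractiveness $P_j^{\gamma}$,
and a distance-decay kernel $f(d) = d^{-\beta}$ (inverse power) or
$f(d) = e^{-\beta d}$ (exponential) over km distances $d_{ij}$ — Euclidean
or road-network. The scaling constant $k$ is fixed by normalisation, never
fitted by the user. Calibration is an exhaustive grid search over
$\gamma \in \{1.2, \ldots, 1.9\}$ (step 0.1) and
$\beta \in \{0.5, \ldots, 3.0\}$ (step 0.25) for both kernels, scored by
SRMSE (with MAE and MAPE reported alongside) of projected against observed
end-of-interval populations. Because census stocks identify only *net*
migration, the default calibration matches the predicted net-migration
volume to the growth-adjusted census change; see the methods vignette
(`vignettes/gravity-migration-modelling.Rmd`) for the identification
argument.

Also included: Riley's Terrain Ruggedness Index from DEM rasters with
settlement-level quantile classes, road-network distance matrices with
nearest-node snapping, regional flow aggregation with a relative-difference
benchmark panel, thresholded flow-network exports, and TRI-group migration
statistics.

## Worked example

Generate a synthetic settlement system (60 settlements, Zipf populations,
gravity flows with Poisson noise under ground-truth parameters
$\gamma^* = 1.5$, $\beta^* = 1.0$, power kernel), calibrate, and inspect:

```r
library(gravityflow)

cfg   <- synthetic_config(n_settlements = 60, seed = 19)
world <- generate_world(cfg)
cal   <- grid_search(world$settlements, world$distances, "t0", "t1")
cal
#> <calibration_result> interval t0-t1: 176 grid rows, objective srmse
#> best: power decay, gamma = 1.4, beta = 1 (SRMSE 0.0046, MAE 12.71, MAPE 0.53%)
```

The search evaluates all 176 grid configurations and lands one 0.1 step
off the true $\gamma$ at this small, noisy size (at n = 200 the truth is
recovered within one grid step in ≥ 90% of seeds, and exactly on
noiseless worlds). `glance()` returns the selected row with the derived
scaling constant and migration volume:

```r
glance(cal)
#> # A tibble: 1 × 11
#>   interval family gamma  beta           k total growth_factor   srmse   mae  mape objective
#>   <chr>    <chr>  <dbl> <dbl>       <dbl> <dbl>         <dbl>   <dbl> <dbl> <dbl> <chr>
#> 1 t0-t1    power    1.4     1 0.000000363 4639.          1.05 0.00463  12.7 0.529 srmse
```

Here `total` is the calibrated net-migration volume (≈ 4639 movers) and
`growth_factor` the national natural-increase ratio (1.05) absorbed before
flows are inferred. Downstream analytics chain directly:

```r
rug   <- ruggedness_table(tri(world$dem), world$settlements)
flows <- predict_flows(world$settlements, world$distances, best_params(cal), wave = "t0")
top_destinations(flows, rug, k = 3)
#> # A tibble: 3 × 3
#>   destination  flow  rank
#> 1 S0001       2101.     1
#> 2 S0002        246.     2
#> 3 S0008        196.     3
```

Migrants from the most rugged quintile overwhelmingly head to the largest
settlement — the urban-attractor pattern the model is built to expose.
`autoplot(cal)` draws the calibration surface; `run_pipeline()` executes
the whole chain from CSV inputs to artefacts plus a reproducibility
manifest.

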