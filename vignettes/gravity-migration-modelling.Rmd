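---
title: "Modelling settlement-level internal migration with gravity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling settlement-level internal migration with gravity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gravityflow)
library(dplyr)
```

## The problem

Long-run census series record the *stock* of population in each settlement
at each wave, but not the *flows* between settlements. gravityflow
reconstructs plausible origin–destination migration flows from those stocks
with an unconstrained (total-constrained) spatial interaction model,
calibrates its two behavioural parameters against the observed intercensal
population change, and quantifies how terrain ruggedness structures the
resulting net-migration geography. Everything is exercisable on synthetic
settlement systems with known ground truth, so the whole pipeline — from
distance matrices to parameter recovery — is testable without any external
data.

## The model

The flow from origin $i$ to destination $j$ over one intercensal interval
is

$$F_{ij} = k \, P_i \, P_j^{\gamma} \, f(d_{ij}), \qquad i \ne j,$$

where $P_i$ is the origin population at the start of the interval,
$P_j^{\gamma}$ is destination attractiveness (population raised to the
scaling exponent $\gamma$), and $f$ is a distance-decay kernel: inverse
power $f(d) = d^{-\beta}$ (dimensionless $\beta$, heavier tail, favoured
where long-distance moves matter) or exponential
$f(d) = e^{-\beta d}$ ($\beta$ per km, faster decline). Self-flows are
structurally excluded, which also avoids the $d = 0$ singularity of the
power kernel. $\beta$ is family-specific and never compared across
families; both families are always calibrated.

The constant $k$ only sets the overall volume. `normalise_k()` implements
the total-constrained reading literally: $k = T / \sum_{i \ne j} P_i
P_j^{\gamma} f(d_{ij})$, so predicted flows sum to a supplied total $T$
exactly.

## What census stocks identify, and the calibration identification choice

Stocks at two waves give, after removing natural change, only the *net*
balance of each settlement. `derive_targets()` absorbs natural increase
into one national factor $g = \sum P(\text{end}) / \sum P(\text{start})$
(the simplest construction that isolates migration from natural change),
defines the per-settlement target $\Delta_i = P_i(\text{end}) - g
P_i(\text{start})$ — which sums to zero by construction — and the
migration volume $T = \sum_i \max(0, \Delta_i)$, the volume of net
arrivals.

Because $T$ is a *net* volume while $\sum F_{ij}$ is a *gross* volume,
forcing the gross total to equal $T$ inside the calibration loop shrinks
every predicted net balance by a pattern-dependent factor and biases the
grid search towards high-amplitude flow patterns; on noiseless synthetic
worlds it demonstrably selects the wrong corner of the grid.
`grid_search()` therefore fixes $k$ per grid point by matching the
*predicted net-migration volume* $\sum_i \max(0, \widehat{net}_i)$ to $T$
(`k_constraint = "net_volume"`, the default). This is the identification
consistent with what the data measure: on a noiseless world whose true
parameters lie on the grid, the true configuration is recovered exactly,
which is the package's end-to-end oracle. The literal gross-total
constraint remains available (`k_constraint = "flow_total"`) for
sensitivity analysis, and `normalise_k()` is unchanged for scaling flows
to any externally known gross volume.

## Calibration

`grid_search()` evaluates an exhaustive grid — by default $\gamma \in
\{1.2, 1.3, \ldots, 1.9\}$ and $\beta \in \{0.5, 0.75, \ldots, 3.0\}$ for
both kernels, 176 configurations. The $\beta$ step of 0.25 resolves optima
a half-unit apart while keeping the grid small; exhaustive evaluation is
preferred to optimisation because the surface is cheap and the grid tiny.
Each configuration is scored on projected versus observed end populations
($\hat P_i = g P_i + \widehat{net}_i$, clamped at zero with a diagnostic)
using three complementary statistics:

* **MAE** — mean absolute deviation, in persons;
* **MAPE** — mean absolute percentage error over settlements with nonzero
  observed value (zero-observed entries are excluded with a count rather
  than destabilising the mean);
* **SRMSE** — RMSE divided by the mean observed value, dimensionless and
  comparable across intervals; this is the default selection objective,
  with ties broken deterministically towards smaller $\beta$, then smaller
  $\gamma$, then power before exponential.

```{r calibration}
cfg <- synthetic_config(n_settlements = 60, seed = 19)
world <- generate_world(cfg, noise = "none")
cal <- grid_search(world$settlements, world$distances, "t0", "t1")
glance(cal)
```

The noiseless world above is generated with $(\gamma^*, \beta^*) = (1.5,
1.0)$, power kernel; the search recovers it exactly.

## Distances

`euclidean_matrix()` returns straight-line km for planar coordinates and
great-circle (haversine, Earth radius 6371 km) for lon/lat.
`network_matrix()` snaps each settlement to its single nearest road node
by a straight connector (the simplest deterministic reading of snapping a
settlement to the closest road) and adds shortest-path lengths over the
graph. Unreachable pairs are an error, never an arbitrary large distance:
a distance matrix with infinities would silently poison the gravity
kernel. When every edge is at least as long as its straight-line chord,
network distances dominate Euclidean ones pair by pair (triangle
inequality); `elongation_summary()` reports the per-pair ratios and flags
any ratio below 1 as a data fault. Note that network and Euclidean
matrices coincide only on pairs joined by a direct detour-1 edge; for
non-adjacent pairs the network path is strictly longer unless the
intermediate nodes are collinear.

## Terrain ruggedness

`tri()` implements the Riley formulation: for each interior cell, the
square root of the sum of squared elevation differences to its eight
neighbours, in metres. Border cells and cells with any missing neighbour
are nodata — partial neighbourhoods would bias the index low. The index is
translation invariant and scales linearly with elevation, both asserted in
the tests. `settlement_tri()` averages TRI cells within a circular buffer
(default radius 2 km — a typical settlement footprint; the zonal unit is a
package parameter, since cadastral polygons are not part of the inputs),
falling back to the nearest valid cell when the buffer is empty.
`quantile_groups()` classifies settlements into $k = 5$ groups by ranked
TRI, ties broken by settlement id so the classification is deterministic;
group 5 is the most rugged.

## The synthetic world

The generator defines the study conditions under which every downstream
claim is tested:

* **Populations** follow the deterministic rank-size rule
  $P_r = \mathrm{round}(P_1 r^{-s})$ with $s = 1$ (classic Zipf) and a
  top population of 50\,000 — deterministic rather than sampled so that
  examples are analytically checkable.
* **Coordinates** mix a uniform background with Gaussian clusters
  (fraction 0.6, spread 10 km) in a 300 km × 200 km box, emulating
  clustered settlement systems at national scale.
* **Roads** are the Gabriel graph of the settlement points (it contains
  the Euclidean MST, hence is connected) with per-edge lognormal detour
  factors truncated at 1 (meanlog $\log 1.25$, sdlog 0.1 — typical road
  circuity of 1.2–1.4).
* **Terrain** is a sum of anisotropic Gaussian ridges plus smoothed noise
  on a regular grid covering the box.
* **Flows** follow the gravity law under known parameters
  ($\gamma^* = 1.5$, $\beta^* = 1.0$, power), normalised to a gross
  volume $T = m \sum P$ with mobility $m = 0.05$ per interval (a typical
  decadal gross internal-migration intensity), with independent Poisson
  counts around the expectation — a standard count-noise model, switchable
  off for noiseless oracles. Natural increase is one uniform factor
  $g = 1.05$.
* **Seeding**: one master seed split into named substreams
  (settlements / dem / roads / flows), so regenerating one layer never
  perturbs the others.

End populations are $\mathrm{round}(g P_i) + in_i - out_i$, clamped at
zero with a loud diagnostic when clamping touches more than 1% of
settlements.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatially correlated demographic shocks, age
structure, international migration, policy-driven relocations,
multi-interval coupling (each interval is simulated independently), and
road networks with junction nodes away from settlements.

```{r recovery}
noisy <- simulate_interval(
  generate_settlements(synthetic_config(n_settlements = 200, seed = 1)),
  euclidean_matrix(generate_settlements(synthetic_config(n_settlements = 200, seed = 1))),
  synthetic_config(n_settlements = 200, seed = 1)
)
best_params(grid_search(noisy$settlements,
                        euclidean_matrix(noisy$settlements), "t0", "t1"))
```

With Poisson noise at these volumes (gross $T \approx 1.5 \times 10^4$),
the recovered parameters stay within one grid step of the truth in at
least 90% of seeds — the statistical acceptance property, tested over 20
fixed seeds.

## Regional benchmarking

`aggregate_regions()` collapses settlement flows to region-to-region
totals (intra-regional moves between distinct settlements included), and
`relative_difference()` compares predicted against observed regional
matrices cellwise: $RD_{ab} = (\hat R_{ab} - R_{ab}) / R_{ab}$, positive
meaning overestimation. Cells with zero observed flow are undefined and
reported as a dash by default, matching how such benchmark tables are
printed; an opt-in $\varepsilon$ mode ($\varepsilon = 10^{-9}$ by default)
divides by the stabiliser instead. `regional_comparison()` assembles the
full panel with row/column/grand totals — printed totals can be supplied,
because historical tables often total unrounded values, so the printed
marginals may differ from rounded-cell sums by a count or two. Display
rounding is 2 decimals; stored values keep full precision.

## Reporting

`export_flow_network()` keeps edges with flow strictly above 1 migrant
(the conventional noise cut; flows are real-valued and are not rounded
first) while node inflow/outflow/net are computed before thresholding, so
node attributes remain conserved quantities. `flow_distributions()` uses
log10 bins of width 0.25 anchored at the smallest positive value (zeros
and negatives counted separately) plus 20 equal-width linear bins, and
reports the adjusted Fisher–Pearson sample skewness.
`tri_migration_stats()` summarises net migration per TRI group with
quartiles and 5th/95th percentiles under the linear-interpolation
order-statistics convention; absolute counts are the default, with a
per-capita option, since absolute figures understate pressure on small
mountain settlements. `top_destinations()` ranks destinations of flows
originating in the most rugged group, ties broken by id.

## Numerical choices and degenerate inputs

* Sums use R's long-double accumulation; conservation identities are
  asserted to 1e-9 relative tolerance.
* Zero off-diagonal distances (duplicate coordinates) are validation
  errors, not silently accepted inputs.
* A zero migration volume ($T = 0$) yields $k = 0$ and all-zero flows.
* All-equal quantile inputs warn and fall back to id-order grouping.
* Grid rows with non-finite metrics are flagged and excluded from
  selection with a warning, never silently dropped.

## Problem sizes

The test suite works at deliberately modest scales — toy systems of 2–12
settlements for closed-form and oracle checks, 20–60 settlements for
property tests, and 200 settlements over 20 seeds for the recovery
experiments — chosen so the full suite documents the method's behaviour
at sizes where exhaustive oracles (double loops, Floyd–Warshall,
scalar arithmetic) remain exact and cheap.

## Limitations

The model reduces migration to population mass and distance: no
covariates, no origin/destination constraints (the production-,
attraction- and doubly-constrained variants are out of scope), no travel
time or one-way restrictions, and the net-volume identification cannot
recover gross flow volumes from stocks — reported flow magnitudes are
calibrated to net census change and should be read accordingly.
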