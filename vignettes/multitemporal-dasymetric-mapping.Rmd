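---
title: "Multi-temporal dasymetric population mapping: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-temporal dasymetric population mapping: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdasym)
```

## The model

`popdasym` produces gridded population surfaces from admin-unit census
counts by *top-down dasymetric redistribution*: within each unit the count
is split across cells in proportion to a weighting surface, so unit totals
are conserved by construction. The weighting surface comes from a
regression forest whose response is the log population density of admin
units,

$$y_z = \ln\left(\frac{\mathrm{pop}_z}{\mathrm{area}_z}\right),$$

with the area taken over *non-excluded* cells only, and whose features are
zonal aggregates of a gridded covariate stack (means for continuous layers,
majority codes for categorical ones). The fitted forest is then evaluated
at every cell's covariate values; $w_i = \exp(\hat y_i)$ on habitable
cells, $w_i = 0$ on excluded ones. Because the surface is renormalized
within each unit, only within-unit weight ratios matter — which is why no
log-back-transform bias correction (smearing) is applied: any multiplicative
correction cancels in $w_i / \sum_{j \in z} w_j$. For the same reason the
physical unit of the density response (per km² vs per hectare) only shifts
$y$ by an additive constant and cancels after renormalization; the package
uses cells' native squared length units and does not expose a unit choice.

Two assumptions matter. First, people live only on cells outside the
exclusion mask (protected areas plus a 200-unit buffer around the coastline
and main roads); training density, prediction support and redistribution
all use that same support, and the synthetic ground truth respects it too
(see below). Second, in the transferred scheme M1, covariate–density
relationships are assumed stable across years — the point of the M1/M2
comparison is to test what that assumption costs.

## The temporal dimension

Settlement (built-up percentage) layers exist only at a few epochs
(the defaults emulate the 1975/1990/2000/2014 satellite epochs), while
censuses fall between them. `interpolate_builtup()` fills the gap linearly:

$$B_t = B_{t_1} + \frac{t - t_1}{t_2 - t_1}\,(B_{t_2} - B_{t_1}),$$

with the epoch pair chosen by `select_bracketing_epochs()`. Linearity is
the weakest assumption available absent information on within-interval
settlement growth; endpoints reproduce the epoch layers exactly, outputs
are clamped to [0, 100] (the quantity is a percentage), nodata propagates,
and extrapolation outside the epoch span is refused rather than guessed.
Nonlinear (e.g. spline) settlement interpolation is deliberately out of
scope. Land cover is handled by an era rule: one static map can serve a
range of years (`landcover_era_map`), mirroring the common situation where
temporally explicit land cover exists only for recent years.

The two training schemes are:

* **M1** — fit once on the year with the most spatially detailed census
  (here, the finest admin level), predict every year's weights from that
  year's own covariate stack. Exploits detail; assumes stable
  relationships.
* **M2** — fit one model per year on that year's (coarser) census.
  Tracks relationship drift; pays with fewer training units.

Validation follows the reaggregation design: coarse-level counts are
redistributed and the resulting surface is summed within finer held-out
units, scored by RMSE and MAE on raw counts (a per-capita variant would
divide by unit population; errors against census counts are the
convention). The coarse counts used for redistribution are always derived
by aggregating the evaluation-level census upward, never taken as an
independent input — this guarantees that residuals cancel within each
coarse unit (conservation transfer) and makes zero error attainable in the
self-consistency case. `run_pipeline()` exposes a `final_scheme` choice for
which scheme's surfaces are written as the final maps, defaulting to M1:
when one year has much more detailed training data than the rest,
consistency across the series argues for transferring that single model.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `buffer_distance` | 200 | length units (abstract m) | exclusion buffer around coastline and main roads; two cells at the default 100 m resolution |
| `rf_params(trees)` | 500 | — | conventional regression-forest size; stochastic-replicate runs in the tests use 300 for runtime with no qualitative change |
| `rf_params(mtry)` | ⌊p/3⌋ | features | the regression-forest convention |
| `rf_params(min_node_size)` | 5 | zones | regression default; `Inf` yields constant (root-only) trees, the areal-weighting oracle |
| `n_permutations` | 5 | — | permutation replicates for %IncMSE; importance is an average over seeded shuffles |
| `exclusion_buffer` (generator) | 200 | length units | the truth surface is zero on the same buffered support the method assumes |
| `noise_sd` (generator) | 0.3 | log-density sd | ≈ 35% multiplicative cell-level noise, a realistic residual after covariates |
| `rural_baseline` (generator) | 0.02 | relative density | unsettled rural cells stay populated rather than empty — zero built-up does not mean zero people |

## The synthetic generator

`generate_scene()` builds the full study environment from one seed:
nested admin zones (Voronoi growth on seeded cells, merged upward by
k-means so nesting is guaranteed), a smooth elevation field with derived
slope, road/river/coastline masks, three protected discs, a 9-class
land-cover map, built-up layers whose settlement cores grow in extent and
intensity across epochs, and a true population surface per census year:
log density is a linear combination of log-scaled covariates
(`density_coefficients`, optionally differing per year to express
relationship drift) plus Gaussian noise, exponentiated, floored by the
rural baseline, zeroed on the uninhabitable support, and scaled within each
coarse zone so zone totals follow compound growth. Default per-zone annual
growth rates are drawn from 2.76–3.71%, the range observed across
fast-growing coastal districts over 1979–2009; the default domain total
starts at 10⁶ people. Census tables at every level are exact zonal sums of
the truth, so nesting conservation and the closed-form growth ratio hold to
machine precision.

One generator decision deserves its own paragraph. Early versions zeroed
truth only on protected areas; on desk-scale grids the settlement core
often sits on the coastal road, and up to ~80% of the true population could
then fall inside the 200 m buffers — cells where the method, by its stated
exclusion, must place nobody. Scoring the method against a truth that
violates the method's own support assumption measures the assumption, not
the weighting. The generator therefore zeroes truth on the full exclusion
mask (protected + buffers) by default (`exclusion_buffer = 200`), making
truth and method agree on where people can live; set `exclusion_buffer = 0`
to study the misspecified case deliberately.

What the generator does *not* emulate: realistic urban morphology (cores
are smooth exponential decays, not street grids), geographic coordinates
and geodesic distance (everything is planar with an abstract cell size —
the method's logic is projection-free), boundary changes between censuses,
and census undercount. Passing tests therefore demonstrate the *mechanics*
(conservation, schema stability, scheme trade-offs under controlled drift),
not performance on any real country's data.

## Numerical choices and degenerate inputs

* Conservation is tested at relative tolerance 1e-9; in practice the
  redistribution identity holds to ~1e-15 because counts are stored as
  reals. An optional largest-remainder integerization
  (`integerize_counts()`) is provided for realism; it changes table totals
  by less than one person.
* Zonal majority ties break toward the smallest class code; zone
  rasterization assigns a cell to the zone whose seed is nearest, ties to
  the smallest zone id — both deterministic and order-independent.
* The distance transform is an exact Euclidean distance transform, not a
  chamfer approximation; a distance-to layer for a class absent from the
  domain is a constant grid-diagonal with a warning, so the feature schema
  stays fixed across years (the forest needs identical feature sets for
  training and prediction).
* Admin units with zero population or zero unmasked area have no definable
  log density; they are dropped from training with a message rather than
  given an epsilon (an epsilon would leak an arbitrary constant into the
  response). Fewer than 10 usable units is an error.
* Zones whose predicted weights sum to zero but whose census count is
  positive fall back to uniform allocation over their unmasked cells (all
  cells if fully masked), with a warning.
* Per-year M2 forests draw seeds from a common stream (`seed + year
  index`): reproducible, but no coupling between years.
* Only the built-up percentage layer represents settlements by default; a
  distance-to-settlement layer is available behind
  `build_stack(include_dist_builtup = TRUE)` for users who want both.

## Problem sizes used in the tests

The unit suite runs on 60×60-cell scenes with a 4/20/60 zone hierarchy.
The acceptance checks use a 200×200 scene with 8/40/200 zones and four
census years for conservation at scale, and twenty replicate 80×80 scenes
with 4/24/96 zones for the stochastic claims: forest weighting recovering
truth better than areal weighting (strong built-up signal, no drift), the
built-up covariate ranking first in %IncMSE, and the M1/M2 winner pattern
when drift is concentrated in the year most distant from M1's training
year. These sizes were chosen as the smallest at which the zone hierarchy
and buffer geometry are non-trivial; all results cited in the README are
computed by the test suite or `scripts/acceptance.R`, nothing is
hand-entered.

## Known limitations

RMSE/MAE comparisons between schemes are qualitative (winner patterns over
seeded replicates), not calibrated to any particular country's error
magnitudes. The forest gives no pixel-level uncertainty. Spatially varying
(per-region) forests, covariate selection, population projection to
non-census years, and statistical significance tests of scheme differences
are out of scope.
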