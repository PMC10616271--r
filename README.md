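# persistgrid

Long-term species persistence under land conversion and climate warming,
on gridded landscapes.

`persistgrid` is for macroecologists who have (or want to simulate)
three things on a common grid of coarse squares (think 10 × 10 km cells
over a region): two-epoch categorical land-use rasters, per-square
temperature series, and opportunistic occurrence records from two
recording periods. It models the persistence (1) or extirpation (0) of
each species' populations square by square,

```
persist/extirpate ~ land conversion * temperature change
                    + recorder effort + microclimate + PCNM spatial axes
```

fitting five nested logistic formulations per species (controls only,
+conversion `L`, +warming `ΔT`, additive, interactive), selecting by AIC,
and summarising effects as average marginal effects (AMEs): the mean of
`(β_v + β_int w_i) p_i (1 − p_i)` over a species' occupied squares, scaled
to +0.1 °C/decade of warming or +10 percentage points of conversion.

Around that core the package implements:

* **Land-use change metrics** — harmonisation of native map classes onto
  six broad categories, nearest-neighbour resampling, mutual masking with
  geometry buffers, per-square category fractions, fractional change,
  the conversion fraction `L`, and pixel-fate transition matrices.
  Rasters travel as plain-text ESRI ASCII grids.
* **Outcome rules** — a change in status is only accepted where another
  species of the same taxon was recorded in the relevant square and
  period; species in ≤ 100 first-period squares are excluded; complete
  (and quasi-) separation is screened before fitting.
* **Frescalo** — the frequency-scaling recorder-effort model: weighted
  neighbourhoods (geographic proximity × Sorensen community similarity),
  per-square effort multipliers standardised to a taxon target Φ, time
  factors and decadal distribution trends, plus the Telfer index as an
  independent cross-check.
* **Interaction meaningfulness** — for species whose best model is
  interactive, an 11 × 11 decile prediction grid (121 paired predictions)
  compares the interactive and additive fits via paired t-tests against a
  Bonferroni family threshold, plus a decile-by-effect-size species table.
* **Reporting** — response cohorts (`T+`, `T−`, `L+`, `L−`, `++`, `+−`,
  `−+`, `−−`), a cohort × trend-sign chi-square test, and machine-readable
  run summaries.
* **A synthetic world generator** — seeded landscapes with known truth
  (category mixes, Beta conversion intensities through a transition
  kernel, a warming surface with a tunable conversion–warming correlation,
  logit-linear species, effort-biased detection), so the whole pipeline is
  testable by parameter recovery with no external data.

## Worked example

Generate a synthetic world, quantify land-use change, and fit the model
suite for one species:

```r
library(persistgrid)
library(dplyr)

w <- generate_world(synth_config(seed = 42))
#> <synthetic_world> 16x16 squares, 60 species, 10862 records (seed 42)

transition_matrix(w$raster_hist, w$raster_mod, from_category = 2)
#> # A tibble: 6 × 4
#>    from    to     n proportion
#>   <int> <int> <int>      <dbl>
#> 1     2     1   894    0.0537
#> 2     2     2  9082    0.546
#> 3     2     3  2161    0.130
#> 4     2     4   612    0.0368
#> 5     2     5   138    0.00829
#> 6     2     6  3753    0.226
```

Semi-natural grassland (category 2) retains 55% of its pixels; most of the
rest became improved grassland (6) and arable (3). Now the model suite for
a species whose true response is additive (generated with strong positive
warming and negative conversion effects):

```r
covars <- w$square_table |>
  mutate(E = E1) |>
  select(square_id, L, dT, E, M, pcnm1, pcnm2)
d <- truth_outcomes(w) |>
  filter(species_id == "sp003") |>
  inner_join(covars, by = "square_id")

fits <- fit_formulations(d)
fits[, c("formulation", "k", "logLik", "AIC", "converged")]
#>   formulation     k logLik   AIC converged
#> 1           1     5  -84.1  178. TRUE
#> 2           2     6  -81.8  176. TRUE
#> 3           3     6  -78.8  170. TRUE
#> 4           4     7  -72.6  159. TRUE
#> 5           5     8  -71.7  159. TRUE

best <- select_best(fits)
#> <persist_fit> formulation 4, n = 152, AIC = 159.16

average_marginal_effect(best, "dT", unit = 0.1)
#>   variable  unit   ame
#> 1 dT         0.1 0.237
bootstrap_ci(best, n_sim = 100, seed = 1, ame_variables = c("dT", "L"))
#>   term        estimate    lower   upper
#> 1 ...
#> 3 dT           15.0      9.00   26.1
#> 8 AME_dT        0.237    0.147   0.342
#> 9 AME_L        -0.0663  -0.0927 -0.0358
```

AIC picks the additive formulation (the generating one). The AME says this
species' persistence probability rises by about 24 points per extra
0.1 °C/decade of warming and falls by about 6.6 points per 10% of its
squares converted; the parametric bootstrap intervals cover the generating
raw-scale coefficients (12.8 and −3.40). `run_pipeline(run_config(...),
out_dir)` chains every stage — change metrics, climate trends, outcomes,
Frescalo, model suite, interaction assessment, cohorts — and persists each
stage's output as CSV/JSON in `out_dir`.

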