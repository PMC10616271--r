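---
title: "Modelling species persistence under land conversion and climate warming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling species persistence under land conversion and climate warming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persistgrid)
library(dplyr)
```

## The problem

Long-term biological recording schemes let us ask whether a species that
occupied a 10 km grid square early in the twentieth century still occupies
it today. `persistgrid` models that binary outcome — persistence (1) versus
extirpation (0) of a population in a coarse grid square — as a function of
two slow environmental drivers measured over the same squares:

* **land conversion** `L`: the fraction of fine land-cover pixels inside the
  square whose harmonized category differs between a historical and a
  modern map, and
* **climate warming** `dT`: the per-square linear trend of mean temperature,
  in degrees C per decade,

together with controls for recorder effort, microclimatic variability and
spatial autocorrelation. The package covers the full chain: raster change
metrics, outcome construction from opportunistic records, the Frescalo
recorder-effort model, a five-formulation logistic model-selection suite
with average marginal effects, a decile-grid procedure that decides whether
an interactive response is *meaningful*, and cohort-level reporting. A
seeded synthetic-world generator with known truth makes every stage
testable by parameter recovery, with no external data.

## Land-use change metrics

Rasters are single-band categorical grids (`cat_raster`), exchanged as
plain-text ESRI ASCII grids. The analysis harmonizes both epochs onto six
broad categories (urban, semi-natural grassland, arable, woodland, inland
water, improved grassland), resamples by nearest neighbour, and masks both
epochs to an identical valid footprint — including an optional buffer
(default 75 map units) around linear features such as roads, which
historical sheets drew far too wide. Within each coarse square we compute
per-category fractions, their between-epoch difference (`fractional_change`,
summing to zero across categories), the overall conversion fraction `L`,
and pixel-fate transition matrices (`transition_matrix`) whose rows are
probability vectors. For habitat specialists, `specialist_change` swaps the
generic `L` for one category's fractional change so that positive values
mean retention or gain of the focal habitat.

Temperature trends are ordinary least-squares slopes of annual mean
temperature on year, multiplied by ten. Monthly series are averaged to
annual means first: a plain OLS slope on monthly values would carry strong
seasonal autocorrelation for no gain in the trend estimate. Squares with
fewer than three annual values are dropped and flagged. Taxon-specific
windows (plants 1961–99, birds 1973–2006, Lepidoptera 1961–2004) are
configuration, not code.

## Outcomes from opportunistic records

Presence in both periods is persistence; presence then absence is only
accepted as extirpation when *another species of the same taxon* was
recorded in that square in the second period — otherwise the square was
plausibly unvisited and the pair is excluded rather than scored.
Colonisations are collected under the symmetric period-1 coverage rule and
feed only the distribution-trend analysis. Species recorded in 100 or fewer
unique squares in the first period are excluded (the threshold is
exclusive: 101 squares is kept). Before any model is fitted, each species
is screened for complete separation — predictor ranges under the two
outcomes that do not overlap, under which the logistic MLE diverges.
Quasi-separation (ranges touching at a point) is treated as separation by
default, since it equally prevents a finite estimate; affected species are
removed from species- and taxon-level analyses alike.

## Frescalo: recorder effort and distribution trends

Recording effort varies enormously across space and time, and raw
frequencies confound effort with occupancy. For each square we take the
`G = 200` geographically nearest squares, rank them by Sorensen similarity
of their recorded communities, keep the `K = 100` most similar, and weight
them `w = (1 - (r_sim - 1)/K)^4 (1 - (r_dist - 1)/G)^4`, so the target
itself always has weight 1. Weighted neighbourhood frequencies `f_ij` are
then standardised: the sampling-effort multiplier `alpha_i` solves

```
mean over benchmark species of (1 - (1 - f_ij)^alpha_i) = phi
```

by bisection to a residual below 1e-8, where `phi` is the taxon's standard
neighbourhood frequency (defaults here: birds 0.92, butterflies 0.86,
macromoths 0.67, plants 0.75). `alpha_i` exceeds 1 exactly where the local
frequencies fall short of `phi`, i.e. in under-recorded squares, so the
*recorder effort* covariate used downstream is the reciprocal `1/alpha_i`:
removing records from a square strictly raises its `alpha` and lowers its
effort estimate, which is the behaviour the property suite asserts. The
benchmark set is the top `ceiling(0.27 R_i)` species by local frequency,
with `R_i = sum_j f_ij` the expected local richness; because rescaling is
monotone in `f`, ranking by raw or rescaled frequency is identical and the
seemingly circular definition collapses. The fraction is configurable.

Per-species, per-period time factors `TF_jt` solve
`sum over visited squares of (1 - (1 - f*_ij)^TF) = n_jt` for the observed
number of occupied squares, on the pooled-data rescaled frequencies; when
the equation has no finite root (a species observed in every usable square)
the factor is capped at 99 and flagged. The decadal trend is
`(TF_2 - TF_1)` divided by the interval between period midpoints in
decades; only its sign is consumed downstream, which is robust to the
pooled-`f*` simplification. As an independent cross-check the Telfer index
regresses logit second-period range proportion on logit first-period
proportion across species, weighted by `N2 p2 (1 - p2)` (the inverse
binomial variance of the logit), and standardises the residuals; species at
proportion 0 or 1 are excluded.

## The model suite

Five nested logistic formulations are fitted per species to the
persistence outcomes: controls only; + conversion; + warming; additive;
and interactive (`L * dT`). The controls — recorder effort, microclimate,
and the first two PCNM eigenvectors — appear in all five. PCNM axes come
from `vegan::pcnm` (distance truncation at the longest minimum-spanning-tree
edge, far pairs replaced by four times the threshold, double-centring,
eigen-decomposition); we unit-normalise each axis and fix its sign so the
first nonzero loading is positive, and the test suite checks the result
against an independently coded dense PCoA oracle.

Covariates are z-scored internally before the IRLS fit — purely a
conditioning choice — and every reported coefficient is back-transformed to
the raw covariate scale; the two parameterisations have identical
likelihood, which the tests verify against an unstandardised `glm` fit.
Fits are polished by Newton steps until the score norm falls below 1e-8
(at most 100 IRLS + 25 polish iterations); anything else is reported
non-converged and excluded from selection with a warning. Selection is by
minimum AIC with exact ties broken toward fewer parameters. The taxon-level
analogue adds a species random intercept through `lme4::glmer` and reports
the latent-scale marginal and conditional R-squared
(`R2m = s2_f / (s2_f + s2_u + pi^2/3)`).

Effect sizes are average marginal effects: the sample mean of
`(b_v + b_int w_i) p_i (1 - p_i)` scaled to conventional increments —
0.1 degrees C per decade for warming, ten percentage points for conversion —
so an AME of +0.02 reads "persistence probability higher by 2 points per
increment". Requesting the AME of a variable absent from a model is an
error, never a silent zero. Intervals are parametric bootstrap percentiles
(default 100 simulations, seeded): outcomes are redrawn from the fitted
probabilities and the same formulation refitted.

## When is an interaction meaningful?

For species whose best model is interactive, statistical preference by AIC
does not by itself mean the interaction changes predictions materially. We
therefore predict persistence over an 11 x 11 grid per predictor — observed
minimum, the nine deciles (linear-interpolation quantiles), and maximum —
with controls at their medians, from both the interactive and the additive
fit, giving 121 paired predictions. A paired t-test per species is compared
to a Bonferroni threshold `alpha/m` for the m-species family (for a
230-species family at alpha 0.05 this is 0.000217). Degenerate cases are
explicit: all-zero differences give p = 1; constant nonzero differences
give an infinite t and p = 0, flagged either way. Degrees of freedom are
reported honestly as valid pairs minus one. A companion table sorts, for
each decile row of one predictor, each species' largest absolute prediction
difference across the other predictor's eleven values into size bins; rows
sum to the species count. The max statistic (rather than mean or per-cell
counts) is a deliberate, config-switchable choice: it answers "could the
interaction matter anywhere along the other gradient".

## Cohorts and reporting

Species with non-interactive environmental best models are sorted into
eight response cohorts by coefficient sign (`T+`, `T-`, `L+`, `L-`, and the
four additive sign pairs, warming first); coefficient sign equals AME sign
for these models, so the realisation is unambiguous. Controls-only,
interactive, and exactly-zero-coefficient species are excluded with
recorded reasons, and the bookkeeping identity — cohorts plus every
exclusion class equals the analysed species — is asserted in the tests.
A Pearson chi-square on the 8 x 2 cohort-by-trend-sign table tests whether
persistence responses translate into national range trends; zero-trend
species are dropped and counted, and empty cohort rows reduce the degrees
of freedom, which are reported as computed.

## The synthetic world

`generate_world()` builds the study design the pipeline assumes, from one
seed:

* **Historical raster.** A Gaussian random field (iid normals circularly
  convolved with a Gaussian kernel, weights normalised so the marginal
  stays N(0,1); bandwidth 3 pixels by default) thresholded at *empirical*
  quantiles, so the realised composition matches the configured mix to
  rounding error. The default mix — urban 4%, semi-natural grassland 65%,
  arable 22%, woodland 6%, water 3%, improved grassland 0% — reflects a
  mid-century British landscape in which improved grassland was still at
  trace levels.
* **Conversion.** Each square draws a conversion intensity from a
  Beta(2, 3); converted pixels are chosen with category-dependent weights
  (semi-natural grassland most exposed) and re-assigned through a
  row-stochastic transition kernel whose default sends converted grassland
  mostly to improved grassland and arable.
* **Warming correlated with conversion.** Two smooth coarse fields are
  empirically orthonormalised; warming is an affine function of the first,
  and the conversion field mixes the two with a weight solved numerically
  (`uniroot`) so the *realised* Pearson correlation between `L` and `dT`
  equals `rho_LT` (default 0.5, within the 0.38-0.58 range typical of
  such landscapes) to ~1e-6 on every seed. A target beyond what the
  Beta-transformed field can express is an explicit error, never a silent
  clip.
* **Species.** Per-taxon coefficient distributions on the
  standardised-covariate scale (so "strong effect" means ≥ 0.5 per SD),
  with the generating formulation assignable per species. The truth table
  also stores the implied raw-scale coefficients, computed with the
  all-square means and SDs, so fitted raw-scale coefficients compare
  directly. Period-1 occupancy is Bernoulli per square; period-2 occupancy
  combines survival from the logit-linear persistence model with
  dispersal-limited colonisation — the per-square colonisation probability
  scales with the species' period-1 prevalence. Without that scaling a
  constant colonisation rate makes rare species gain range proportionally
  far faster than common ones, which distorts any relative (cross-species)
  change index; with it, relative and absolute change rank species
  consistently.
* **Detection.** `P(detect) = 1 - (1 - q_j)^E_it` with per-species
  detectability q and lognormal square-by-period effort; zero effort means
  no records.

What the generator does *not* emulate: real geography (coastlines, missing
squares), temporally clustered recording visits, taxonomic misdetection,
within-square abundance, and range contiguity beyond field smoothness.
Passing tests therefore demonstrate correctness of the estimators under
the stated statistical structure, not robustness to every pathology of
real atlas data.

## Numerical choices and test conditions

* Effort and time-factor equations: bisection, |residual| < 1e-8 (solver
  tolerance 1e-12); time factors capped at 99 when no finite root exists.
* Logistic fits: score-norm 1e-8; AIC ties toward fewer parameters;
  percentile bootstrap with 100 simulations.
* Quantiles: linear interpolation (type 7) throughout.
* Flagged Frescalo squares (degenerate benchmark frequencies) are excluded
  from time-factor equations rather than imputed.
* The test and acceptance suites use worlds sized to finish on one CPU in
  minutes while leaving the criteria decisive: a 16 x 16-square default
  world; a 40 x 40-square high-occupancy world (~1500+ occupied squares
  per species) for formulation recovery, AME sign agreement and bootstrap
  coverage; 20 x 20-square worlds for the Frescalo effort CV, thinning
  monotonicity and trend-versus-Telfer checks, the latter pooled over
  three seeds because the per-world species count (~30 large-change
  species) leaves a single world's agreement fraction noisy.

## Limitations

The Frescalo benchmark convention and the pooled-`f*` time-factor
weighting are documented approximations validated by the property suite,
not by square-level comparison against any particular historical
implementation. The mixed-model path reports, but does not resolve,
singular random-intercept fits. The interaction table's per-row statistic
is one of several defensible conventions; switch `statistic = "mean"` to
see how much it matters. Range trends use only two periods; no standard
errors are attached to time factors.
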