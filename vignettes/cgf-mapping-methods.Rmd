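---
title: "Methods: model-based geostatistics for child growth failure mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based geostatistics for child growth failure mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgfmap)
```

This vignette is the package's own account of its statistical methods: the
model and its assumptions, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the design decisions taken where the design was genuinely open.

## From child measurements to binomial observations

**LMS z-scores.** A measurement `x` (height in cm for HAZ, weight in kg for
WAZ, weight given a height band for WHZ) maps to
`z = ((x/M)^L - 1)/(L * S)`; when `|L| < 1e-8` the limiting form
`log(x/M)/S` is used, so the transform is continuous in the skewness power.
A child is afflicted when `z < -2`, *strictly*: ties at the threshold do
not count. The package ships smooth synthetic LMS tables (`synthetic_lms_table`)
— deliberately *not* the WHO 2006 reference values, which are licensed
tables the package does not redistribute; `read_lms_table()` loads external
tables in the same `(indicator, sex, index, L, M, S)` layout. The WHZ index
is height rounded to the nearest 1-cm table band; HAZ/WAZ use completed age
in months.

**Exclusions.** Records with missing sex, missing or non-integer age in
months (the practical record-level form of "insufficient age granularity"),
or nonpositive measurements are dropped, as are polygon clusters with a
sample size of one. Biologically-implausible-z flagging exists behind
`flag_z` but is off by default: it is not part of the documented analysis
and changing the default would silently change prevalence.

**Seasonality of WHZ.** Wasting is acute, so WHZ carries a within-year
cycle. Per region, an additive model
`WHZ ~ f_per(month) + f_trend(time) + country` is fitted with mgcv: `f_per`
a cyclic cubic spline on months (knots at 0.5 and 12.5 so January joins
December), `f_trend` a smooth over the study span, country effects shrunk
random-effect offsets by default. The source text describes the country
term both as fixed and as random; we default to shrunk (`country_effect =
"fixed"` gives dummies) because with few clusters per country-month an
unshrunk dummy absorbs seasonal signal. Only the *centered* periodic
component (mean zero over months 1-12) is subtracted from each record, so
the long-term trend and level are untouched; with uniformly represented
months the annual mean is unchanged to numerical precision. Records without
an interview month cannot be adjusted and are dropped from the wasting
analysis.

**Polygon observations.** Clusters located only to an admin unit are
resampled: 10,000 locations drawn proportionally to pixel population
(uniformly jittered within a pixel), reduced to `k` k-means centroids
(MacQueen, 200 iterations; the reduction needs proxies, not the exact
optimum), with weight = cluster share of the 10,000 draws. `k` is not
stated in the source methodology; the default `min(10, populated pixels)`
keeps the likelihood small while representing within-polygon heterogeneity,
and weights sum to one so a polygon contributes exactly one observation's
worth of information. Weighted likelihood semantics: each pseudo-observation
contributes `w_j` times the binomial log-likelihood of the parent's
`(C, N)` at its location.

## The geostatistical model

Per region, cluster counts are binomial with

```
logit(p_i) = X_i' beta + Z(s_i, t_i) + eps_i
```

* `X_i`: out-of-sample logit-scale predictions of the three stacked child
  learners — a penalized-spline additive binomial smoother (mgcv, `k = 5`
  per covariate, double-penalty selection), boosted trees (xgboost,
  logistic loss, depth 3, learning rate 0.1, 150 rounds), and an
  L1-penalized logistic regression with internally cross-validated penalty
  (glmnet). Features stay in the link space and are never centre-scaled, so
  the sum-to-one constraint on `beta` is meaningful. Stacking folds are
  plain random observation-level folds (5 by default); the spatially
  stratified folds are reserved for validation. Pixel-level prediction uses
  the full-data (in-sample) learner fits.
* `beta`: simplex-constrained weights, parameterized by a gauge-fixed
  softmax with a flat Dirichlet(1) prior (whose log-density in softmax
  coordinates adds `sum(log beta_k)`, mildly repelling the boundary).
* `Z`: zero-mean Gaussian process with Kronecker covariance — Matérn in
  space (smoothness `nu = 1`, matching the common SPDE `alpha = 2`
  convention in two dimensions, under the `sqrt(8 nu)` range convention so
  correlation is ~0.14 at one range) times AR1 over years.
* `eps_i`: independent nugget; observations sharing a pixel-year share the
  field value but not the nugget. Nugget noise is excluded from predicted
  surfaces (it is observation-level), behind `include_nugget` if wanted.

### Inference engine

The separable Kronecker field is *exactly* a linear-Gaussian state-space
model across years: state `f_t` over P pixels, stationary start
`f_1 ~ N(0, S_Matern)`, transition `f_t = rho f_(t-1) + e_t` with
`e_t ~ N(0, (1 - rho^2) S_Matern)`. The engine (`fit_geostat`) therefore:

1. forms working Gaussian observations (empirical logits first, then
   iterated penalized-quasi-likelihood refreshes at the smoothed fit, 2
   outer passes by default) with variance `(1/(N p q) + tau^2) / w`;
2. maximizes the penalized working marginal likelihood — evaluated by one
   Kalman filter pass per proposal — over `(log range, log sigma^2,
   log tau^2, logit((rho+1)/2), softmax weights)` with Nelder-Mead
   (`maxit = 300` default; Brent when one parameter is free);
3. approximates hyperparameter uncertainty by a Gaussian at the mode
   (finite-difference Hessian, step 0.01, eigenvalue-floored inverse);
4. draws `n_theta_draws` (15 default) hyperparameter configurations and,
   conditional on each, joint field draws over all pixels and years by
   forward-filter backward-sampling; candidate maps inherit the
   configuration's `beta`.

Priors (the source does not publish its own): log-normal(0, 1.5^2) on
range, field s.d. and nugget s.d.; standard normal on `logit((rho+1)/2)`.
These are weakly informative on a world measured in pixel units.

The Kalman pass is validated against a brute-force dense multivariate
normal over the Kronecker covariance in the unit tests, and the whole
Gaussian approximation against an exact random-walk Metropolis backend
(`fit_geostat_mcmc`, prior-shaped proposal adapted to ~23% acceptance) on a
30-pixel-year instance; the acceptance suite requires the posterior mean
discrepancy to stay under 0.05 logit units. The PQL treatment of the nugget
(absorbed into working observation noise rather than kept as a latent
block) is the one approximation the oracle comparison does not isolate; the
comparison instance therefore fixes `tau^2 = 0` so the two routes target
the same latent object.

**Numerical choices.** Log-scale parameters are clamped to ±25 before
exponentiation so optimizer excursions cannot underflow; the Matérn matrix
over a grid is evaluated once per unique distance and scattered back;
covariances receive a relative jitter of 1e-8 before factorization, and
near-singular conditional covariances in the sampler fall back to an
escalating ridge then an eigenvalue clip. Learner predictions and all
latent surfaces are clipped to ±12 on the logit scale before inversion.
Degenerate responses (all zeros or all ones) make the learners fall back to
a clipped pooled constant with a warning; fits refuse fewer than 10
observations and unresampled polygon rows.

## Post-estimation

Candidate maps aggregate to admin2/admin1/national levels by year-matched
population weighting over unmasked pixels. Raking factors are computed *per
draw* as the ratio of the national series value to that draw's national
aggregate at anchors 2000/2005/2010/2015 (2015 interpolated between the
series' 2010 and 2016 entries) and linearly interpolated between anchors;
every pixel in a country-year is multiplied by its factor. Raked prevalence
is clamped at 1 — the source is silent on factors pushing prevalence past
its support — and clip events are counted on the cube; with no clipping,
post-raking national aggregates equal the series at anchors to 1e-10 per
draw (an acceptance criterion). A consequence worth knowing: at anchor
years the national-level posterior interval collapses onto the series value
by construction; subnational intervals retain their width.

Masking sets excluded pixels (in the synthetic world: minimum population
below `mask_pop_threshold`) to the nodata sentinel in all products.
Population-weighted tail classes sort pixels by value with ties broken by
pixel index and take the maximal prefix whose cumulative population does
not exceed the tail fraction, so the "lowest 10%" always holds at most 10%
of the population and the rule is deterministic.

**Projections and targets.** Annual rates of change are differences of
logit posterior-mean prevalence between adjacent years of 2000-2015,
averaged with weights proportional to `(t - 2000)^gamma`, `gamma = 1`
(linear recency weighting; `gamma = 0` is the plain mean). 2025 prevalence
is `invlogit(logit(p_2015) + 10 * AROC)`. Projections are computed from the
*raked* mean series: raking is multiplicative on the probability scale, so
it does change logit differences (a property the test suite documents
explicitly), and the calibrated series is the one whose trend we mean.
Relative targets resolve as `(1 - reduction) *` the population-weighted
2010 aggregate over the whole modelled domain; wasting uses the fixed 5%
level. Attainment probability at pixel level is the fraction of draws below
the target; at admin level the fraction of draws whose *unit aggregate* is
below the target (a population-weighted mean of pixel probabilities is
available behind `method = "pixel_mean"`, since the corresponding map
caption can be read either way). Pace of progress uses the achieved decline
`-AROC` against the decline required to reach the target in ten years, both
on the logit scale for internal consistency (the figure legends' "annualized
decrease" does not pin the scale); ratios above 4 land in the ">400%"
class, non-declining pixels in their own class, and pixels at or below the
target are "met".

## Validation

`spatial_folds()` builds five holdouts from whole admin units ordered by a
seeded adjacency sweep, balanced within one unit. `cv_metrics()` reports
mean error, RMSE, 95% coverage and sample-size-weighted Pearson correlation.
Coverage is *data-level*: the predictive interval for `C/N` mixes binomial
sampling noise over the prevalence draws (exact binomial mixture per
observation; a normal mixture for pooled unit-year counts), because
observed proportions are noisy realizations — a latent-prevalence interval
would be systematically anti-conservative against them. Both definitions
exist in the literature; data-level is the primary one here.

`compare_formulations()` fits, on identical folds: stacked features with
and without the space-time field, raw-covariate (weighted binomial GLM)
means with and without the field, and the field alone. For the raw
formulations the GLM coefficients are profiled out first and enter the
engine as a fixed offset (their sampling uncertainty is not propagated —
a pragmatic choice that only affects the two baseline formulations).

## The synthetic world: what it emulates, and what it does not

`make_world()` builds a rectangular pixel world with nested rectangular
admin partitions, a smooth log-normal under-5 population with 2% annual
growth, and standardized covariate layers: a deterministic space + time
trend, a static layer, and temporally drifting layers. Covariate surfaces
mix broad structure with pixel-scale detail; the fine component matters
because real raster covariates vary below the residual field's range — a
world whose covariates are all smoother than the Matérn range cannot
distinguish "covariate signal" from "spatial residual", and the ensemble
versus GP comparison would be unidentified. Coordinates are abstract pixel
units with Euclidean distances: map projections are cartography, not
statistics. Truth surfaces are covariate means (linear by default; a
`covariate_effect` function injects nonlinearities and interactions) plus
one exact draw of the Matérn x AR1 field via its state-space form. Surveys
place point clusters at population-weighted pixels and polygon clusters
over admin2 units (default mix 60% points — a free choice; the source only
bounds the GPS share from below), with around 30 measured children per
cluster (a typical survey-cluster yield) and counts binomial at the
pixel-year truth; per-child microdata are generated through the inverse LMS
transform so the anthropometry module reproduces the counts exactly, and a
12-month sinusoid (amplitude 0.4 z-units for wasting) is injected on the
continuous z-score, mirroring a measurement-level seasonal process. The
national benchmark series is the population-weighted national truth at
2000/2005/2010/2016 with optional logit-scale noise; worlds default to
2000-2016 so the 2016 benchmark exists while estimation covers 2000-2015.

It does **not** emulate: realistic geography or road-network-like cluster
placement, survey design effects and sampling weights, age-specific
prevalence structure, measurement error or digit preference in
anthropometry, non-binomial overdispersion at cluster level, or missing-data
mechanisms beyond simple record deletion. Passing tests therefore show the
*pipeline* recovers what it assumes — correct models, correctly wired — not
that those assumptions hold in any real survey system.

## Problem sizes used by the test and acceptance suites

The recovery/calibration study runs the conditions the package treats as
its reference experiment: a 20 x 20 pixel, 2000-2016 world, 150 point
clusters per year, truth with range 6 pixels, field variance 0.5, annual
autocorrelation 0.8, and well-specified features (intercept plus one
covariate each, so the simplex combination spans the true mean); ten seeded
replicates in the tests, five in `scripts/acceptance.R`, each fitted with
`maxit = 120` and 6 hyperparameter configurations over 200 draws. The
formulation comparison uses a 12 x 12 world over 2000-2007 with 50 clusters
per year, nonlinear covariate effects with an interaction, and a residual
field at the default variance. The end-to-end pipeline test runs an 8 x 8
world with 20 draws. These sizes are desk-scale by design; `n_draws = 1000`
reproduces the candidate-map count used for full analyses.

## Known limitations

* Empirical-Bayes hyperparameter treatment understates hyperparameter
  uncertainty relative to a full posterior; the calibration acceptance band
  (90-98% at nominal 95%) is how the package checks this matters little at
  the study scale.
* The PQL working model can bias variance components when cluster sizes are
  very small (a handful of children); cluster sizes below ~10 deserve the
  MCMC backend for comparison.
* Per-draw raking with clamping at 1 can break anchor-year exactness
  exactly where clipping occurs; the clip counter on the cube is the audit
  trail.
* Stacked-learner uncertainty is not propagated into the geostatistical
  model (features enter as fixed covariates), matching the source
  methodology and its stated computational constraint.
* The dense state covariance limits a single region to a few thousand
  pixels; continental-scale grids need the sparse machinery this package
  deliberately does not implement.
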