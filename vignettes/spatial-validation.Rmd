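---
title: "Validating geospatial prediction models under spatial autocorrelation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating geospatial prediction models under spatial autocorrelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large-scale environmental maps — forest aboveground biomass (AGB) at 1-km
resolution being the motivating case — are usually built by training a
machine-learning model on point samples (here, inventory-backed reference
pixels) with remote-sensing and environmental covariates, and validated by
random K-fold cross-validation. Both the mapped variable and its covariates
are spatially autocorrelated: reference AGB shows structure to roughly
120 km, and climate, topographic and optical covariates to roughly
250–500 km. Field samples are aggregated into dense clusters separated by
large unsampled swaths. Under these conditions a randomly selected test
pixel is nearly always surrounded by training pixels much closer than the
autocorrelation range, so the train/test independence assumption of random
cross-validation fails: a model can score well by interpolating its
training data in space, with no transferable environmental signal at all.

`geocv` packages the machinery needed to measure this effect and to
validate such models honestly:

* empirical semivariograms (Matheron estimator) with weighted model fits
  and practical-range estimation, applied to responses, covariates, and
  cross-validation residuals;
* spatially blocked K-fold CV by complete-linkage clustering of the
  distance matrix cut at height `H`, which bounds every within-fold
  distance by `H`;
* buffered leave-one-out CV (B-LOO): one test sample per model run, all
  training samples within radius `r` excluded, swept over radii, with an
  extrapolation safeguard;
* baseline models — an intercept-only null model and a coordinates-only
  random forest (RF_XY) — against the covariate random forest (RF_RSE);
* a reverse diagnostic predicting sample coordinates from covariates;
* a Gaussian-random-field scenario generator reproducing the data
  structure above with a controllable true effect, so every claim can be
  tested against a known truth.

## The synthetic landscape generator

Covariates are independent stationary Gaussian random fields simulated by
dense Cholesky factorization of the covariance matrix (exact at the few
thousand points used here; the implementation caps a single field at 8000
points). The exponential model uses the practical-range parameterization
`C(h) = sill * exp(-3h/range)`, so "range" means what a practitioner reads
off an empirical variogram: the distance where correlation has decayed to
5%. Coordinates are planar km in an abstract projection — at study scale
all distances are treated as planar throughout, so no geodesy enters the
simulation or the analysis.

The response is

```
y(s) = sum_j beta_j x_j(s) + e_spatial(s) + e_iid(s)
```

with `e_spatial` an independent GRF and `e_iid` white noise. Two canonical
study conditions are exported:

* `spurious_skill_config()`: 2000 samples in 40 clusters of 50 (cluster
  scale 20 km) on a 1000 x 1000 km extent; five exponential covariates
  with a 300 km range and unit sill; `beta = 0`; response an independent
  exponential field with a 120 km range and unit sill plus iid noise
  contributing 10% of the total response variance (`sd = 1/3`). Every unit
  of covariate-model "skill" measured here is leakage, by construction.
* `genuine_skill_config()`: 1000 uniform samples, three 300-km covariates
  with `beta = (1,1,1)` and `iid_noise_sd = 1`, so the linear signal
  drives 75% of the response variance and there is no spatially
  structured residual. A sound validation scheme must report substantial
  skill here.

Defaults that the data structure does not pin down were fixed once on
field-realistic grounds: 40 clusters of 50 emulate inventory campaigns of
roughly the real density (the real dataset splits into 44 spatial folds at
H = 150 km); the 20 km cluster scale reproduces "dense patches, empty
swaths" nearest-neighbour bimodality; the response field's default nugget
fraction is 0.3 of its sill (the empirical nugget of 1-km AGB is not
established; the value is exposed in `scenario_config()` and the
spurious-skill condition instead uses a pure 120-km field plus explicit
10% iid noise). The generator emulates second-order structure (ranges,
sills, nuggets, clustering) but not real-data features such as
non-Gaussian, skewed AGB distributions, anisotropy, covariate
cross-correlation, or measurement artifacts — so passing tests demonstrate
the validation machinery, not the behaviour of any particular real map.

## Cross-validation strategies

**Random K-fold** (`random_kfold_split()`, default K = 10): uniform
partition, sizes within one of each other; the conventional, leakage-prone
baseline.

**Spatial K-fold** (`spatial_kfold_split()`, default H = 150 km): complete
linkage guarantees every within-fold pairwise distance is at most `H`; the
fold count K emerges from the data. `H` should sit slightly beyond the
response's practical range. Metrics are computed on the pooled out-of-fold
prediction vector in both K-fold modes.

**B-LOO** (`bloo_cv()`): per repetition, `n_test` test samples are drawn
without replacement (repetition seeds are `seed + rep`, so repetitions are
independent but reproducible); for each test sample and radius `r`, all
samples within the closed ball of radius `r` are excluded from training —
"within distance r" is read inclusively, and at `r = 0` exactly the test
location is excluded, making it plain leave-one-out. Defaults follow the
motivating design: 16 radii (0 to 150 by 10 km), 100 test samples, 10
repetitions — 16,000 model fits per model spec. R2 and RMSPE are computed
per (repetition, radius) over the pooled test predictions, then summarized
as mean ± SD over repetitions.

The extrapolation safeguard: a candidate test sample is accepted only if,
after removing neighbours at the *largest* radius, each of its covariates
still lies within the training column's [min, max] (categorical levels
must be present). The check runs at the largest radius only — training
sets only grow as `r` shrinks, and the point of the safeguard is to keep
covariate-space extrapolation error out of the distance sweep. Rejected
candidates are redrawn up to a budget of `50 * n_test` per repetition;
beyond it the repetition proceeds with fewer test samples and the count is
reported, so pathological scenarios terminate instead of spinning.

Models: random forests are fit with `ranger` (500 trees,
`mtry = ceiling(p/3)`, minimum node size 5 by default — conventional
regression-forest settings, all exposed), single-threaded with a fixed
seed so every prediction is reproducible bit for bit. The null model
predicts the training mean. Note one metric pathology worth knowing:
under leave-one-out the null prediction `(S - y_i)/(n-1)` is a decreasing
affine function of `y_i`, so its squared Pearson correlation with the
observations is exactly 1 — squared-correlation R2 is meaningless for the
null model, which is why null-model comparisons are made on RMSPE.

## Variogram numerics

The Matheron estimator bins pairs into half-open intervals
`[edge, edge + bin_width)`; empty bins are `NA`, never 0. Defaults:
10 km bins, maximum lag half the maximum pairwise distance. Model fitting
is bounded weighted least squares (`L-BFGS-B`; `range <= 2 * max lag`,
`sill <= 1.2 * max semivariance`, `nugget >= 0`) with Cressie-style
weights `pair_count / lag^2`. Raw pair-count weights were tried first and
discarded: long-lag bins hold most pairs but fluctuate with the
realization, and under count weights the fitted sill and range
occasionally diverge by two orders of magnitude; `N/h^2` weighting (the
default of standard variogram-fitting software) anchors the fit near the
origin where the range is identified. The practical range is reported as
the distance where the fitted curve reaches 95% of `sill + nugget`; an
essentially flat variogram returns a "no structure" flag rather than a
number. Range estimation here is a diagnostic: the generating ranges are
recovered to within ~25% (verified at 120 and 300 km over 10 seeds on a
1500-km window — a 1000-km window holds too few independent patches of a
300-km field to pin its range).

The MCWD recursion `WD_n = min(0, WD_{n-1} + P_n - PET_n)` is iterated
circularly to its fixed point (two passes when any month replenishes);
perennial-deficit climatologies, where the recursion has no fixed point,
fall back to the single-cycle deficit from a zero start, keeping
`|CWD| <= sum(PET)`. Dry-season runs wrap the Dec-Jan boundary and
equal-length runs are disambiguated by severity. Seasonality uses the
population SD — the 12 months are the whole climatological population.
One known reporting discrepancy: published summaries of this covariate
set list an NDII maximum slightly above 1, impossible for the normalized
form `(NIR - SWIR)/(NIR + SWIR)` implemented here; the standard form is
kept and the discrepancy simply noted.

The pixel filters take their boundary semantics literally from their
field definitions: cover "less than 89%" removed (89 kept), "fewer than
3" plots removed, loss "greater than 5%" removed (5 kept), "nonnull" fire
removed, spectral values "more than 10 SD" from the band mean removed in
a single pass (mean and SD of the stage input, population SD). Note an
arithmetic bound worth remembering when testing such filters: among
`n - 1` identical values and one outlier the population z-score is exactly
`sqrt(n - 1)` whatever the outlier's magnitude, so a 10-SD screen cannot
fire on fewer than 102 rows.

## Problem sizes used in the shipped analyses

The packaged analyses and acceptance checks run the spurious-skill
condition at n = 2000 with a reduced B-LOO design — 50 test samples, 3
repetitions, radii 0 to 150 by 30 km, 50-tree forests, averaged over 3
master seeds — which reproduces the qualitative structure of the full
16,000-run design at desk scale; the genuine-skill control runs at
n = 1000 with 200-tree forests. These sizes are the package's own choice
of demonstration scale: the contrasts they measure (random-CV skill vs.
B-LOO skill beyond the response range, RF vs. null RMSPE) are large
relative to the Monte-Carlo spread at this scale.

## Limitations

* Dense-Cholesky simulation caps single-field size (8000 points); the
  pipeline itself has no such cap.
* No anisotropy, no directional variograms, no kriging, no space-time
  fields; coordinates are planar km.
* The extrapolation safeguard brackets covariates marginally (per-column
  ranges), not jointly; points inside every marginal range can still be
  outside the joint data cloud.
* Spatial K-fold with very uneven cluster sizes inherits the usual
  instability of blocked CV metrics; fold sizes are reported so users can
  judge.
* Exponential GRFs are rough (Matérn ν = 1/2): their short-range
  increments behave like noise, so synthetic covariates geolocate samples
  to a fraction of the study extent rather than to a few kilometres.
  Real covariate stacks — smooth interpolated climate surfaces with
  continental trends — pin location much more precisely, which is why the
  reverse-geolocation diagnostic is far sharper on real data than on
  these synthetic landscapes.
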