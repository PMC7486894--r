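# geocv — spatial cross-validation diagnostics for geospatial prediction models

Large-scale environmental maps (the motivating case: 1-km forest
aboveground biomass, AGB, in Mg ha⁻¹) are typically built by training a
random forest on point samples and validated with random K-fold
cross-validation. When the response and its covariates are spatially
autocorrelated over distances far larger than the spacing between
clustered samples, random CV breaks its own independence assumption: test
pixels sit amid spatially proximate training pixels, and a model can look
skilful by interpolating its training data in geographic space rather
than by capturing any environmental relationship.

`geocv` provides the machinery to detect and quantify that failure mode,
and to validate such models honestly:

* **Semivariogram diagnostics** — Matheron estimator
  γ(h) = (1/2N(h)) Σ (zᵢ − zⱼ)², weighted model fits (exponential /
  spherical, Cressie N/h² weights), practical-range estimation, and
  residual variograms of CV predictions.
* **Spatial K-fold CV** — complete-linkage clustering of the distance
  matrix cut at height H (default 150 km) guarantees every within-fold
  pairwise distance ≤ H; the fold count K emerges from the data.
* **Buffered leave-one-out CV (B-LOO)** — one test sample per fit, all
  training samples within radius r excluded, swept over radii (default
  0–150 km by 10), with an extrapolation safeguard that rejects test
  samples whose covariates leave the training domain after maximal
  buffering.
* **Baselines** — an intercept-only null model (training-mean predictor)
  and a coordinates-only forest (RF_XY) against the covariate forest
  (RF_RSE); metrics R² (squared Pearson correlation), RMSPE, and relative
  RMSPE (% of mean observed).
* **Reverse geolocation diagnostic** — predict sample coordinates from
  covariates; success means covariate combinations pinpoint location, the
  mechanism behind hidden spatial interpolation.
* **Synthetic landscapes** — Gaussian-random-field scenario generator
  (exponential/spherical/nugget models, clustered sampling layouts,
  controllable true effects) so every claim is testable against known
  truth.
* **Pixel filters and derived covariates** — the QC exclusion chain
  (vegetation cover, plot count, disturbance, spectral outliers) and
  derived climate/spectral layers (water availability, monthly water
  deficit, dry-season length/severity, maximal climate water deficit,
  seasonality, EVI2, NDII).

## Worked example

A landscape where the covariates *cannot* predict the response (β = 0;
response is an independent 120-km-range field), sampled in dense clusters:

```r
library(geocv)

set <- build_scenario(spurious_skill_config(seed = 42))
covs <- covariate_names(set)
rf <- rf_covariates_spec(covs, n_trees = 50, seed = 1)

# conventional random 10-fold CV
cv_r <- run_kfold_cv(rf, set, random_kfold_split(nrow(set), 10, seed = 2))

# spatially blocked CV (complete linkage, H = 150 km)
folds_s <- spatial_kfold_split(set[, c("x_km", "y_km")], H = 150)
cv_s <- run_kfold_cv(rf, set, folds_s)

round(c(random_r2 = cv_r$metrics$r2, spatial_r2 = cv_s$metrics$r2), 3)
#>  random_r2 spatial_r2
#>      0.383      0.022
```

Random CV credits a no-signal model with R² ≈ 0.4; spatial blocking
reveals the truth (R² ≈ 0). The B-LOO sweep shows the same collapse as a
function of distance — by r ≥ 120 km (the response's autocorrelation
range) the covariate forest's error has converged to the null model's:

```r
curve <- bloo_cv(list(rf, null_model_spec()), set,
                 radii = seq(0, 150, 30), n_test = 50, n_reps = 3, seed = 3)
subset(as.data.frame(curve), radius_km %in% c(0, 120, 150),
       c(model, radius_km, r2_mean, rmspe_mean))
#>     model radius_km r2_mean rmspe_mean
#>      NULL         0  1.0000      1.025
#>      NULL       120  0.3515      1.044
#>      NULL       150  0.3263      1.046
#>    RF_RSE         0  0.4528      0.748
#>    RF_RSE       120  0.0632      1.046
#>    RF_RSE       150  0.0347      1.052
```

(The null model's "R² = 1" at r = 0 is the known squared-Pearson
pathology of leave-one-out mean predictions, which is why null-model
comparisons use RMSPE.)

The numbered scripts under `analysis/` run this narrative end to end
(simulation → variograms → CV comparison → B-LOO curve → geolocation
diagnostic), writing tables under `results/`.

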