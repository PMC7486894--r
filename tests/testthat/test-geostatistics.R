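# Distances, semivariograms, and range estimation.

test_that("pairwise distances: 3-4-5 triangle, zero diagonal, brute force", {
  d <- pairwise_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5)
  expect_equal(unname(diag(d)), c(0, 0))

  xy <- toy_coords(10, seed = 2)
  d <- pairwise_distances(xy)
  for (i in 1:10) for (j in 1:10) {
    expect_identical(d[i, j], d[j, i])
    expect_equal(d[i, j], sqrt(sum((xy[i, ] - xy[j, ])^2)))
  }
  expect_error(pairwise_distances(rbind(c(0, 0), c(Inf, 1))), "finite")
})

test_that("constant field has zero semivariance in every populated bin", {
  xy <- toy_coords(12)
  vg <- empirical_variogram(rep(3.2, 12), xy, bin_width = 20, max_lag = 120)
  pop <- vg$pair_count > 0
  expect_true(all(vg$semivariance[pop] == 0))
  expect_true(all(is.na(vg$semivariance[!pop])))
})

test_that("collinear hand example: all six pairs enumerate correctly", {
  coords <- cbind(c(0, 1, 2, 3), c(0, 0, 0, 0))
  vg <- empirical_variogram(c(0, 1, 0, 1), coords, bin_width = 1, max_lag = 4)
  expect_equal(vg$pair_count, c(0L, 3L, 2L, 1L))
  expect_true(is.na(vg$semivariance[1]))
  expect_equal(vg$semivariance[2:4], c(0.5, 0, 0.5))
})

test_that("Matheron estimator equals brute-force pair enumeration", {
  for (s in 1:3) {
    xy <- toy_coords(50, extent = 80, seed = s)
    z <- rnorm(50)
    edges <- seq(0, 60, by = 12)
    vg <- empirical_variogram(z, xy, bin_width = 12, max_lag = 60)
    bf <- brute_force_variogram(z, xy, edges)
    expect_equal(vg$pair_count, bf$pair_count)
    expect_equal(vg$semivariance, bf$semivariance)
  }
})

test_that("variogram is invariant to sample order and quadratic in scale", {
  xy <- toy_coords(40, seed = 4)
  z <- rnorm(40)
  vg <- empirical_variogram(z, xy, bin_width = 15, max_lag = 75)
  perm <- sample(40)
  vg_p <- empirical_variogram(z[perm], xy[perm, ], bin_width = 15, max_lag = 75)
  expect_equal(vg_p$semivariance, vg$semivariance)
  expect_equal(vg_p$pair_count, vg$pair_count)

  vg2 <- empirical_variogram(2 * z, xy, bin_width = 15, max_lag = 75)
  expect_equal(vg2$semivariance, 4 * vg$semivariance)
})

test_that("variogram rejects degenerate inputs", {
  xy <- toy_coords(5)
  expect_error(empirical_variogram(1, xy[1, , drop = FALSE]), "at least 2")
  expect_error(empirical_variogram(rnorm(5), xy, bin_width = 0), "bin_width")
  expect_error(empirical_variogram(rnorm(5), xy, bin_width = 5, max_lag = -1),
               "max_lag")
})

test_that("noiseless exponential curve recovers practical range 120 +/- 1 km", {
  h <- seq(5, 400, by = 10)
  g <- theoretical_semivariance(h, "exponential", 120, 1, 0)
  vg <- data.frame(bin_center_km = h, semivariance = g,
                   pair_count = rep(100L, length(h)))
  attr(vg, "bin_edges") <- seq(0, 400, by = 10)
  attr(vg, "n_samples") <- 100L
  class(vg) <- c("variogram_estimate", "data.frame")
  est <- estimate_range(vg, "exponential")
  expect_false(est$no_structure)
  expect_lt(abs(est$range - 120), 1)
  expect_equal(est$sill, 1, tolerance = 0.01)
})

test_that("flat variogram is flagged as structureless, not given a range", {
  xy <- toy_coords(60, extent = 300, seed = 5)
  vg <- empirical_variogram(rep(0, 60) + 1e-15 * rnorm(60), xy, bin_width = 20)
  est <- estimate_range(vg)
  expect_true(est$no_structure)
  expect_true(is.na(est$range))
})

test_that("range recovery from simulated fields is within 25% of truth", {
  # a 1500 km window can resolve both the short (120 km) and the long
  # (300 km) generating ranges; smaller windows hold too few independent
  # correlation patches for the long case
  for (true_range in c(120, 300)) {
    est <- vapply(1:10, function(s) {
      xy <- toy_coords(1000, extent = 1500, seed = 600 + s)
      z <- simulate_grf(xy, "exponential", range = true_range, sill = 1,
                        seed = 700 + s)
      vg <- empirical_variogram(z, xy, bin_width = 25)
      estimate_range(vg)$range
    }, 0)
    expect_lt(abs(mean(est) - true_range) / true_range, 0.25)
  }
})

test_that("residual variograms expose leakage-dependent structure", {
  cfg <- scenario_config(n_samples = 700, n_clusters = 28, cluster_radius = 15,
                         field_specs = default_covariate_fields(3, 300),
                         iid_noise_sd = sqrt(1 / 9), seed = 21)
  set <- build_scenario(cfg)
  coords <- set[, c("x_km", "y_km")]
  folds <- random_kfold_split(nrow(set), 10, seed = 22)

  perfect <- custom_model_spec("oracle", function(train, test) test$response)
  cv_perfect <- run_kfold_cv(perfect, set, folds)
  vg0 <- residual_variogram(cv_perfect, coords, bin_width = 30)
  expect_true(all(vg0$semivariance[vg0$pair_count > 0] == 0))

  slope_of <- function(vg) {
    ok <- vg$pair_count > 0 & vg$bin_center_km <= 200
    unname(coef(lm(vg$semivariance[ok] ~ vg$bin_center_km[ok],
                   weights = vg$pair_count[ok]))[2])
  }
  cv_null <- run_kfold_cv(null_model_spec(), set, folds)
  slope_null <- slope_of(residual_variogram(cv_null, coords, bin_width = 30))
  expect_gt(slope_null, 0)  # null predictions leave the spatial structure intact

  rf <- rf_covariates_spec(covariate_names(set), n_trees = 100, seed = 23)
  cv_rf <- run_kfold_cv(rf, set, folds)
  slope_rf <- slope_of(residual_variogram(cv_rf, coords, bin_width = 30))
  # randomly cross-validated RF residuals absorb the structure even though
  # the covariates carry no signal about the response
  expect_lt(abs(slope_rf), 0.4 * slope_null)

  bad <- cv_rf; bad$predicted[3] <- NA
  expect_error(residual_variogram(bad, coords), "missing predictions")
})
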