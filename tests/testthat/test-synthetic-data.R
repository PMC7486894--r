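# Gaussian-random-field simulator and scenario generator.

test_that("degenerate process (sill = 0, nugget = 0) returns the constant mean", {
  xy <- toy_coords(15)
  z <- simulate_grf(xy, "exponential", range = 50, sill = 0, nugget = 0,
                    mean = 7, seed = 1)
  expect_identical(z, rep(7, 15))
})

test_that("nugget-only field reproduces the stated variance", {
  xy <- toy_coords(10000, extent = 1000)
  v <- vapply(1:20, function(s) {
    var(simulate_grf(xy, "nugget", sill = 0, nugget = 2, seed = s))
  }, 0)
  expect_lt(abs(mean(v) - 2) / 2, 0.10)
})

test_that("simulated exponential field tracks the theoretical semivariogram", {
  xy <- toy_coords(800, extent = 1000, seed = 3)
  bins <- NULL
  gammas <- matrix(NA_real_, 10, 0)
  acc <- NULL
  for (s in 1:10) {
    z <- simulate_grf(xy, "exponential", range = 120, sill = 1, seed = s)
    vg <- empirical_variogram(z, xy, bin_width = 25, max_lag = 400)
    acc <- if (is.null(acc)) vg$semivariance else acc + vg$semivariance
    bins <- vg$bin_center_km
  }
  mean_gamma <- acc / 10
  theo <- theoretical_semivariance(bins, "exponential", 120, 1)
  # binwise agreement within Monte-Carlo tolerance, averaged over seeds
  expect_lt(max(abs(mean_gamma - theo)), 0.15)
})

test_that("simulation is deterministic under a fixed seed", {
  xy <- toy_coords(50)
  z1 <- simulate_grf(xy, "spherical", range = 60, sill = 2, nugget = 0.5, seed = 9)
  z2 <- simulate_grf(xy, "spherical", range = 60, sill = 2, nugget = 0.5, seed = 9)
  expect_identical(z1, z2)
  z3 <- simulate_grf(xy, "spherical", range = 60, sill = 2, nugget = 0.5, seed = 10)
  expect_false(identical(z1, z3))
})

test_that("invalid parameters are rejected", {
  xy <- toy_coords(5)
  expect_error(simulate_grf(xy, "exponential", range = -5, sill = 1),
               "positive range")
  expect_error(simulate_grf(xy, "exponential", range = 10, sill = -1),
               "non-negative")
  expect_error(simulate_grf(rbind(xy, c(NA, 1)), "nugget", nugget = 1), "finite")
})

test_that("clustered layout: radius 0 collapses members onto the center", {
  xy <- sample_clustered_layout(c(100, 100), 1, 5, 0, seed = 4)
  expect_equal(nrow(xy), 5)
  expect_true(all(xy[, 1] == xy[1, 1]) && all(xy[, 2] == xy[1, 2]))
})

test_that("clustered layout: counts and extent bounds hold", {
  xy <- sample_clustered_layout(c(1000, 600), 44, 50, 20, seed = 5)
  expect_equal(nrow(xy), 2200)
  expect_true(all(xy[, 1] >= 0 & xy[, 1] <= 1000))
  expect_true(all(xy[, 2] >= 0 & xy[, 2] <= 600))
  expect_error(sample_clustered_layout(c(-1, 100), 2, 5, 1), "extent")
})

test_that("clustered layout gives bimodal nearest-neighbor structure", {
  xy <- sample_clustered_layout(c(1000, 1000), 25, 40, 5, seed = 6)
  cl <- attr(xy, "cluster")
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  # within-cluster spacing mode
  within_mode <- median(nn)
  # between-cluster mode: nearest distinct cluster center distances
  centers <- aggregate(xy, by = list(cl), mean)[, -1]
  dc <- as.matrix(dist(centers)); diag(dc) <- Inf
  between_mode <- median(apply(dc, 1, min))
  expect_lt(within_mode * 10, between_mode)
})

test_that("identical scenario configs regenerate identical sample sets", {
  cfg <- scenario_config(n_samples = 120, n_clusters = 6, cluster_radius = 10,
                         field_specs = default_covariate_fields(2, 200),
                         iid_noise_sd = 0.2, seed = 77)
  s1 <- build_scenario(cfg)
  s2 <- build_scenario(scenario_config(
    n_samples = 120, n_clusters = 6, cluster_radius = 10,
    field_specs = default_covariate_fields(2, 200),
    iid_noise_sd = 0.2, seed = 77))
  expect_identical(s1, s2)
})

test_that("beta = (1, 0, 0) with no noise returns the first covariate exactly", {
  cfg <- scenario_config(n_samples = 60, layout = "uniform",
                         field_specs = default_covariate_fields(3, 250),
                         effect_coefficients = c(1, 0, 0),
                         response_spatial = field_spec("rs", "nugget",
                                                       sill = 0, nugget = 0),
                         iid_noise_sd = 0, seed = 8)
  set <- build_scenario(cfg)
  expect_identical(set$response, set$cov1)
})

test_that("with beta = 0 the response is uncorrelated with every covariate", {
  rs <- vapply(1:10, function(s) {
    cfg <- scenario_config(n_samples = 2000, layout = "uniform",
                           field_specs = default_covariate_fields(3, 300),
                           response_spatial = field_spec("rs", "exponential",
                                                         range = 120, sill = 1),
                           iid_noise_sd = 1, seed = 3000 + s)
    set <- build_scenario(cfg)
    max(abs(cor(set$response, set[, covariate_names(set)])))
  }, 0)
  expect_lt(mean(rs), 0.1)
})

test_that("response variance decomposes into spatial sill plus noise variance", {
  tot <- vapply(1:10, function(s) {
    cfg <- scenario_config(n_samples = 2000, layout = "uniform",
                           field_specs = list(), effect_coefficients = numeric(0),
                           response_spatial = field_spec("rs", "exponential",
                                                         range = 120, sill = 1),
                           iid_noise_sd = 0.5, seed = 4000 + s)
    var(build_scenario(cfg)$response)
  }, 0)
  expect_lt(abs(mean(tot) - 1.25) / 1.25, 0.15)
})

test_that("mismatched beta length is an error", {
  expect_error(scenario_config(field_specs = default_covariate_fields(3),
                               effect_coefficients = c(1, 2)),
               "must match")
})

test_that("sample sets round-trip through CSV with provenance sidecar", {
  cfg <- scenario_config(n_samples = 40, n_clusters = 4, cluster_radius = 5,
                         field_specs = default_covariate_fields(2), seed = 12)
  set <- build_scenario(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_set(set, path)
  back <- read_sample_set(path)
  expect_equal(back$response, set$response, tolerance = 1e-12)
  expect_equal(attr(back, "provenance")$response_range, 120)
  expect_setequal(covariate_names(back), c("cov1", "cov2"))
})
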