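# Fold construction, K-fold CV bookkeeping, B-LOO CV, domain safeguard.

test_that("random folds have balanced sizes and are seed-deterministic", {
  f <- random_kfold_split(10, 10, seed = 1)
  expect_equal(sort(unique(f$fold_id)), 1:10)
  expect_true(all(table(f$fold_id) == 1))

  f25 <- random_kfold_split(25, 10, seed = 2)
  sizes <- as.integer(table(f25$fold_id))
  expect_equal(sort(sizes), c(rep(2L, 5), rep(3L, 5)))

  expect_identical(random_kfold_split(100, 10, seed = 5)$fold_id,
                   random_kfold_split(100, 10, seed = 5)$fold_id)
  expect_false(identical(random_kfold_split(100, 10, seed = 5)$fold_id,
                         random_kfold_split(100, 10, seed = 6)$fold_id))
  expect_error(random_kfold_split(5, 10), "K <= n")
})

test_that("complete-linkage folds match the hand dendrogram on collinear points", {
  coords <- cbind(c(0, 10, 200, 210, 500), rep(0, 5))
  f <- spatial_kfold_split(coords, H = 150)
  expect_equal(f$K, 3)
  groups <- split(seq_len(5), f$fold_id)
  expect_setequal(lapply(groups, identity), list(c(1L, 2L), c(3L, 4L), 5L))
  expect_true(all(f$fold_diameters <= 150))
})

test_that("all points within H collapse to a single flagged fold", {
  coords <- toy_coords(10, extent = 50)
  expect_warning(f <- spatial_kfold_split(coords, H = 150), "single spatial fold")
  expect_equal(f$K, 1)
})

test_that("every spatial fold's diameter is bounded by H (brute force)", {
  xy <- sample_clustered_layout(c(800, 800), 15, 20, 30, seed = 31)
  f <- spatial_kfold_split(xy, H = 150)
  expect_gt(f$K, 1)
  for (k in seq_len(f$K)) {
    expect_lte(brute_force_diameter(xy[f$fold_id == k, , drop = FALSE]), 150)
  }
  expect_equal(f$fold_diameters,
               vapply(seq_len(f$K), function(k) {
                 brute_force_diameter(xy[f$fold_id == k, , drop = FALSE])
               }, 0))
})

test_that("null-model 2-fold CV reproduces the hand example", {
  set <- toy_sample_set(c(1, 2, 3, 4), cbind(1:4, rep(0, 4)))
  cv <- run_kfold_cv(null_model_spec(), set, manual_folds(c(1, 1, 2, 2)))
  expect_equal(cv$predicted, c(3.5, 3.5, 1.5, 1.5))
  expect_equal(cv$metrics$rmspe, sqrt(17 / 4))
})

test_that("a memorizing oracle achieves R2 = 1 and RMSPE = 0", {
  set <- toy_sample_set(rnorm(30), toy_coords(30))
  oracle <- custom_model_spec("memo", function(train, test) test$response)
  cv <- run_kfold_cv(oracle, set, random_kfold_split(30, 5, seed = 3))
  expect_equal(cv$metrics$r2, 1)
  expect_equal(cv$metrics$rmspe, 0)
})

test_that("pooled metrics are invariant to fold relabeling", {
  set.seed(8)
  set <- toy_sample_set(rnorm(40), toy_coords(40))
  f1 <- manual_folds(rep(1:4, each = 10))
  f2 <- manual_folds(rep(c(3, 1, 4, 2), each = 10))  # same partition, relabeled
  m <- null_model_spec()
  expect_equal(run_kfold_cv(m, set, f1)$metrics,
               run_kfold_cv(m, set, f2)$metrics)
})

test_that("null-model CV with K = n matches the analytic leave-one-out error", {
  set.seed(9)
  y <- rnorm(15)
  set <- toy_sample_set(y, toy_coords(15))
  cv <- run_kfold_cv(null_model_spec(), set, manual_folds(1:15))
  analytic <- (sum(y) - y) / 14
  expect_equal(cv$predicted, analytic)
  expect_equal(cv$metrics$rmspe, sqrt(mean((y - analytic)^2)))
})

test_that("domain check brackets continuous and categorical covariates", {
  train <- data.frame(a = c(1, 5), b = c(0.2, 0.9), soil = c("x", "y"))
  inside <- data.frame(a = 3, b = 0.2, soil = "y")
  expect_true(domain_check(inside, train, c("a", "b", "soil")))
  expect_true(domain_check(train[1, ], train, c("a", "b", "soil")))
  expect_false(domain_check(transform(inside, a = 6), train, c("a", "b", "soil")))
  expect_false(domain_check(transform(inside, soil = "z"), train, c("a", "b", "soil")))
  expect_false(domain_check(inside, train[0, ], c("a", "b")))

  # brute-force oracle on a random mixed toy
  set.seed(10)
  tr <- data.frame(c1 = rnorm(30), c2 = runif(30), c3 = sample(c("u", "v"), 30, TRUE))
  for (i in 1:20) {
    te <- data.frame(c1 = rnorm(1, sd = 2), c2 = runif(1, -0.5, 1.5),
                     c3 = sample(c("u", "v", "w"), 1))
    manual <- te$c1 >= min(tr$c1) && te$c1 <= max(tr$c1) &&
      te$c2 >= min(tr$c2) && te$c2 <= max(tr$c2) && te$c3 %in% tr$c3
    expect_identical(domain_check(te, tr, c("c1", "c2", "c3")), manual)
  }
})

test_that("B-LOO training sets shrink monotonically and r = 0 is plain LOO", {
  set.seed(11)
  set <- toy_sample_set(rnorm(120), toy_coords(120, extent = 300))
  D <- pairwise_distances(set[, c("x_km", "y_km")])
  radii <- c(0, 40, 80, 160)
  for (i in sample(120, 10)) {
    prev <- NULL
    for (r in radii) {
      train <- which(D[i, ] > r)
      expect_false(i %in% train)
      if (r == 0) expect_equal(length(train), 119)  # only the test point excluded
      if (!is.null(prev)) expect_true(all(train %in% prev))
      prev <- train
    }
  }
})

test_that("B-LOO curve bookkeeping: 16 default radii, reps and test counts recorded", {
  set.seed(12)
  set <- toy_sample_set(rnorm(150), toy_coords(150, extent = 600))
  bc <- bloo_cv(null_model_spec(), set, n_test = 10, n_reps = 2, seed = 13)
  expect_s3_class(bc, "bloo_curve")
  expect_equal(nrow(bc), 16)  # seq(0, 150, by = 10)
  expect_equal(unique(bc$n_reps), 2)
  expect_equal(unique(bc$n_test), 10)
  per_rep <- attr(bc, "per_rep")
  expect_equal(nrow(per_rep), 32)
  # same seed reruns identically
  bc2 <- bloo_cv(null_model_spec(), set, n_test = 10, n_reps = 2, seed = 13)
  expect_equal(as.data.frame(bc2), as.data.frame(bc))
})

test_that("null-model B-LOO RMSPE is flat in the buffer radius", {
  set.seed(14)
  xy <- toy_coords(250, extent = 1000)
  z <- simulate_grf(xy, "exponential", range = 120, sill = 1, seed = 15)
  set <- toy_sample_set(z, xy)
  bc <- bloo_cv(null_model_spec(), set, radii = seq(0, 150, 50),
                n_test = 40, n_reps = 3, seed = 16)
  spread <- diff(range(bc$rmspe_mean))
  expect_lt(spread / mean(bc$rmspe_mean), 0.05)
})

test_that("the extrapolation safeguard rejects out-of-domain test candidates", {
  set.seed(17)
  set <- toy_sample_set(rnorm(60), toy_coords(60, extent = 500))
  set$cov1 <- rnorm(60)
  set$cov1[7] <- 50  # far outside every training range
  spec <- rf_covariates_spec("cov1", n_trees = 20, seed = 18)
  # requesting n - 1 test samples forces every candidate to be screened, so
  # the out-of-domain sample is always examined and always discarded
  bc <- bloo_cv(spec, set, radii = c(0, 50), n_test = 59, n_reps = 1, seed = 19)
  discarded <- attr(bc, "n_discarded_by_safeguard")
  expect_gte(discarded, 1L)  # at least the planted out-of-domain sample
  expect_equal(unique(bc$n_test), 60L - discarded)
})

test_that("a scenario with no admissible test samples raises an error", {
  set <- toy_sample_set(rnorm(5), cbind(c(0, 1, 2, 3, 4), rep(0, 5)))
  # the largest radius exceeds every pairwise distance, so buffering leaves
  # no training data for any candidate
  expect_error(
    bloo_cv(null_model_spec(), set, radii = c(0, 5), n_test = 2, n_reps = 1,
            seed = 20),
    "no admissible test samples")
})
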