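# Competing predictors and prediction metrics.
#
# Three model families are compared throughout: a random forest on
# remote-sensing/environmental covariates (RF_RSE), a random forest on the
# two geographic coordinates alone (RF_XY), and an intercept-only null model
# that always predicts the training mean. That RF_XY tracks RF_RSE, and that
# RF_RSE decays to the null model once nearby training data are excluded,
# are the two signatures of spatially mediated (rather than environmentally
# mediated) predictive skill.

#' Model specifications
#'
#' A `model_spec` bundles a predictor selector with hyperparameters and a
#' seed, and is the unit every cross-validation routine operates on.
#' `null_model_spec()` ignores predictors entirely and predicts the training
#' response mean. `rf_covariates_spec()` (RF_RSE) is a regression random
#' forest on the named covariate columns; `rf_coordinates_spec()` (RF_XY)
#' is the same learner on exactly the two coordinate columns.
#' `custom_model_spec()` wraps an arbitrary `function(train, test)` returning
#' one prediction per test row (useful as a test double).
#'
#' Random-forest defaults follow regression-forest convention: 500 trees,
#' `mtry = ceiling(p / 3)`, minimum node size 5; all are exposed.
#'
#' @param name display name used in reports.
#' @param predictors character vector of predictor columns.
#' @param n_trees,mtry,min_node random-forest hyperparameters (`mtry = NULL`
#'   means `ceiling(p / 3)`).
#' @param seed integer seed making forest training deterministic.
#' @return a `model_spec` list.
#' @export
rf_spec <- function(name, predictors, n_trees = 500, mtry = NULL,
                    min_node = 5, seed = 1L) {
  if (!length(predictors)) stopf("rf_spec needs at least one predictor")
  structure(list(name = name, type = "rf", predictors = predictors,
                 n_trees = as.integer(n_trees), mtry = mtry,
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "model_spec")
}

#' @rdname rf_spec
#' @param covariates covariate columns for the RF_RSE model.
#' @export
rf_covariates_spec <- function(covariates, name = "RF_RSE", n_trees = 500,
                               mtry = NULL, min_node = 5, seed = 1L) {
  rf_spec(name, covariates, n_trees, mtry, min_node, seed)
}

#' @rdname rf_spec
#' @export
rf_coordinates_spec <- function(name = "RF_XY", n_trees = 500, mtry = NULL,
                                min_node = 5, seed = 1L) {
  rf_spec(name, c("x_km", "y_km"), n_trees, mtry, min_node, seed)
}

#' @rdname rf_spec
#' @export
null_model_spec <- function(name = "NULL") {
  structure(list(name = name, type = "null", predictors = character(0)),
            class = "model_spec")
}

#' @rdname rf_spec
#' @param predict_fun `function(train, test)` returning numeric predictions.
#' @export
custom_model_spec <- function(name, predict_fun, predictors = character(0)) {
  stopifnot(is.function(predict_fun))
  structure(list(name = name, type = "custom", predictors = predictors,
                 predict_fun = predict_fun),
            class = "model_spec")
}

#' Train on one set, predict another
#'
#' @param spec a `model_spec`.
#' @param train training sample `data.frame` (must contain `response` and the
#'   spec's predictors).
#' @param test test sample `data.frame` (must contain the predictors).
#' @return numeric predictions, one per test row; deterministic given the
#'   spec's seed.
#' @export
fit_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(train) == 0) stopf("model '%s': empty training set", spec$name)
  if (spec$type == "null") {
    return(rep(mean(train$response), nrow(test)))
  }
  if (spec$type == "custom") {
    return(as.numeric(spec$predict_fun(train, test)))
  }
  missing <- setdiff(spec$predictors, names(train))
  if (length(missing)) {
    stopf("model '%s': predictor column(s) missing: %s", spec$name,
          paste(missing, collapse = ", "))
  }
  p <- length(spec$predictors)
  mtry <- spec$mtry %||% min(p, max(1L, ceiling(p / 3)))
  fit <- ranger::ranger(
    x = train[, spec$predictors, drop = FALSE], y = train$response,
    num.trees = spec$n_trees, mtry = mtry, min.node.size = spec$min_node,
    num.threads = 1L, seed = spec$seed,
    respect.unordered.factors = "partition")
  stats::predict(fit, data = test[, spec$predictors, drop = FALSE],
                 num.threads = 1L)$predictions
}

#' Squared Pearson correlation between observations and predictions
#'
#' The square of the Pearson correlation coefficient — the conventional
#' "R2" of map-validation studies. It is invariant under positive affine
#' transforms of either argument, so it measures association, not
#' calibration. Undefined (returns `NA` with a warning) when either vector
#' is constant; the undefined case is never silently reported as 0.
#'
#' @param observed,predicted numeric vectors, length >= 3.
#' @return scalar in `[0, 1]`, or `NA` when undefined.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stopf("lengths differ")
  if (length(observed) < 3) stopf("need at least 3 pairs")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("R2 undefined for constant vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(observed, predicted)^2
}

#' Root mean squared prediction error
#'
#' `sqrt(mean((observed - predicted)^2))`, in response units.
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @return scalar RMSPE.
#' @export
rmspe <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stopf("lengths differ")
  if (!length(observed)) stopf("need at least one pair")
  sqrt(mean((observed - predicted)^2))
}

#' Relative RMSPE (% of the mean observation)
#'
#' `100 * RMSPE / mean(observed)`, the form in which prediction errors of
#' biomass maps are usually quoted (e.g. an 82 Mg ha-1 error on a 296
#' Mg ha-1 mean is 27.7%).
#'
#' @inheritParams rmspe
#' @return scalar percentage.
#' @export
relative_rmspe <- function(observed, predicted) {
  m <- mean(observed)
  if (m == 0) stopf("relative RMSPE undefined: mean(observed) is zero")
  100 * rmspe(observed, predicted) / m
}

metric_set <- function(observed, predicted) {
  list(r2 = r_squared(observed, predicted),
       rmspe = rmspe(observed, predicted),
       rel_rmspe = if (mean(observed) != 0) {
         relative_rmspe(observed, predicted)
       } else {
         NA_real_
       })
}

#' Predict sample coordinates from their covariates
#'
#' The reverse diagnostic: train a random forest to predict each
#' coordinate from the covariate columns, using `n_train` randomly drawn
#' samples, and evaluate on the held-out remainder. When covariates are
#' spatially smooth, their combination is close to unique per location, so
#' geographic position can be recovered far better than chance — direct
#' evidence that a covariate model can exploit spatial proximity. Two
#' single-output forests sharing a seed are trained, one per coordinate.
#'
#' @param set sample `data.frame`.
#' @param covariates covariate columns (default: [covariate_names()]).
#' @param n_train training rows randomly drawn (default 500).
#' @param n_trees forest size.
#' @param seed integer seed.
#' @return list: `rmse_km` (root mean squared Euclidean distance between
#'   true and predicted locations of held-out samples), `rmse_x_km`,
#'   `rmse_y_km`, `baseline_km` (the no-skill RMS distance of held-out
#'   samples from the training centroid), `n_train`, `n_test`.
#' @export
predict_coordinates <- function(set, covariates = NULL, n_train = 500,
                                n_trees = 500, seed = 1L) {
  covariates <- covariates %||% covariate_names(set)
  if (!length(covariates)) stopf("no covariate columns found")
  n <- nrow(set)
  if (n_train >= n) stopf("n_train (%d) must be < n (%d)", n_train, n)
  idx <- with_seed(seed, sample(n, n_train))
  train <- set[idx, , drop = FALSE]
  test <- set[-idx, , drop = FALSE]
  pred_axis <- function(target) {
    fit <- ranger::ranger(x = train[, covariates, drop = FALSE],
                          y = train[[target]], num.trees = n_trees,
                          mtry = max(1L, ceiling(length(covariates) / 3)),
                          min.node.size = 5, num.threads = 1L, seed = seed)
    stats::predict(fit, data = test[, covariates, drop = FALSE],
                   num.threads = 1L)$predictions
  }
  px <- pred_axis("x_km"); py <- pred_axis("y_km")
  dx <- test$x_km - px; dy <- test$y_km - py
  centroid <- c(mean(train$x_km), mean(train$y_km))
  base <- sqrt(mean((test$x_km - centroid[1])^2 + (test$y_km - centroid[2])^2))
  list(rmse_km = sqrt(mean(dx^2 + dy^2)),
       rmse_x_km = sqrt(mean(dx^2)), rmse_y_km = sqrt(mean(dy^2)),
       baseline_km = base, n_train = n_train, n_test = nrow(test))
}
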