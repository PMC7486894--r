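# Cross-validation engines: K-fold (random or spatial) and buffered
# leave-one-out (B-LOO).
#
# In B-LOO CV a single observation is predicted per model run, with every
# training observation within distance r of it excluded. Sweeping r from 0
# outward shows how much of the apparent skill of a model is carried by
# spatially proximate training data: a model with genuine environmental
# skill keeps its accuracy as r exceeds the response's autocorrelation
# range, whereas a model exploiting spatial proximity decays to the null
# model.

#' K-fold cross-validation
#'
#' Trains the model iteratively on K-1 folds, each time predicting the
#' withheld fold, so every sample receives exactly one out-of-fold
#' prediction from a model never trained on its fold. Metrics are computed
#' on the pooled prediction vector.
#'
#' @param model_spec a `model_spec` (see [rf_spec()]).
#' @param sample_set sample `data.frame` with `response` and the predictors.
#' @param folds a `spatial_folds` covering the sample set, `K >= 2`.
#' @return a `cv_result` list: `observed`, `predicted`, `fold_id`,
#'   `model` (name), `folds_method`, and `metrics` (`r2`, `rmspe`,
#'   `rel_rmspe`).
#' @export
run_kfold_cv <- function(model_spec, sample_set, folds) {
  stopifnot(inherits(model_spec, "model_spec"), inherits(folds, "spatial_folds"))
  n <- nrow(sample_set)
  if (length(folds$fold_id) != n) stopf("folds do not cover the sample set")
  if (folds$K < 2) stopf("K-fold CV needs K >= 2 (got K = %d)", folds$K)
  predicted <- rep(NA_real_, n)
  for (k in seq_len(folds$K)) {
    test_idx <- folds$fold_id == k
    if (all(test_idx)) stopf("fold %d equals the whole sample set", k)
    predicted[test_idx] <- fit_predict(model_spec,
                                       sample_set[!test_idx, , drop = FALSE],
                                       sample_set[test_idx, , drop = FALSE])
  }
  structure(list(observed = sample_set$response, predicted = predicted,
                 fold_id = folds$fold_id, model = model_spec$name,
                 folds_method = folds$method,
                 metrics = metric_set(sample_set$response, predicted)),
            class = "cv_result")
}

#' Covariate-domain membership check
#'
#' `TRUE` iff every continuous covariate of the test sample lies within the
#' `[min, max]` of the corresponding training column, and every categorical
#' level is present in training. Used as the extrapolation safeguard of
#' B-LOO CV: with nearby observations excluded, a prediction outside the
#' training domain would confound spatial-dependence effects with
#' extrapolation error.
#'
#' @param test_sample one-row `data.frame`.
#' @param training_set training `data.frame`.
#' @param covariates columns to check.
#' @return logical scalar (`FALSE` for an empty training set).
#' @export
domain_check <- function(test_sample, training_set, covariates) {
  if (nrow(training_set) == 0) return(FALSE)
  for (v in covariates) {
    x <- training_set[[v]]
    t <- test_sample[[v]]
    if (is.numeric(x)) {
      if (t < min(x) || t > max(x)) return(FALSE)
    } else {
      if (!(as.character(t) %in% unique(as.character(x)))) return(FALSE)
    }
  }
  TRUE
}

#' Buffered leave-one-out cross-validation
#'
#' For each repetition, draws `n_test` test observations (without
#' replacement within a repetition; repetition seeds are `seed + rep`).
#' Candidate test observations are screened by the extrapolation safeguard:
#' training data within the *largest* radius are removed and the candidate
#' is kept only if its covariates still fall inside the training domain
#' ([domain_check()]); rejected candidates are replaced by new draws, up to
#' a budget of `50 * n_test` candidates per repetition, after which the
#' repetition proceeds with fewer test samples (recorded in
#' `n_discarded_by_safeguard`).
#'
#' For every accepted test observation and every radius `r`, all
#' observations within distance `r` of it (closed ball, and always the test
#' point itself) are excluded from training, the model is refit, and the
#' test observation predicted — so the training set at a larger radius is
#' always a subset of that at a smaller one. R2 and RMSPE are computed per
#' (repetition, radius) over the pooled `n_test` predictions, then averaged
#' over repetitions.
#'
#' Several model specs can be evaluated in one sweep; they share the same
#' test draws and exclusion sets, which makes their curves directly
#' comparable and halves the bookkeeping.
#'
#' @param model_specs one `model_spec` or a list of them.
#' @param sample_set sample `data.frame`.
#' @param radii buffer radii (km), strictly increasing; the default
#'   `seq(0, 150, by = 10)` gives 16 radii, i.e. `n_reps * n_test * 16`
#'   model fits per spec at the default 100 x 10 design.
#' @param n_test test observations per repetition.
#' @param n_reps repetitions.
#' @param seed integer master seed.
#' @param domain_covariates columns screened by the safeguard; default: the
#'   union of non-coordinate predictors across the RF specs (empty set
#'   disables the check, as for a null model alone).
#' @return a `bloo_curve` data frame: one row per (model, radius) with
#'   `r2_mean`, `r2_sd`, `rmspe_mean`, `rmspe_sd`, `n_test`, `n_reps`;
#'   attributes `n_discarded_by_safeguard` and `per_rep` (the full
#'   (model, radius, rep) table).
#' @export
bloo_cv <- function(model_specs, sample_set, radii = seq(0, 150, by = 10),
                    n_test = 100, n_reps = 10, seed = 1L,
                    domain_covariates = NULL) {
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  stopifnot(all(vapply(model_specs, inherits, TRUE, "model_spec")))
  names(model_specs) <- vapply(model_specs, `[[`, character(1), "name")
  n <- nrow(sample_set)
  if (n_test >= n) stopf("n_test must be < n")
  radii <- as.numeric(radii)
  if (any(radii < 0) || is.unsorted(radii, strictly = TRUE)) {
    stopf("radii must be non-negative and strictly increasing")
  }
  if (is.null(domain_covariates)) {
    domain_covariates <- unique(unlist(lapply(model_specs, function(s) {
      setdiff(s$predictors, c("x_km", "y_km"))
    })))
  }

  D <- pairwise_distances(sample_set[, c("x_km", "y_km")])
  r_max <- max(radii)
  per_rep <- list()
  n_discarded <- 0L

  for (rep_i in seq_len(n_reps)) {
    candidates <- with_seed(seed + rep_i, sample(n))
    budget <- min(n, 50L * n_test)
    test_idx <- integer(0)
    examined <- 0L
    for (i in candidates) {
      if (length(test_idx) >= n_test || examined >= budget) break
      examined <- examined + 1L
      train_max <- which(D[i, ] > r_max)
      ok <- length(train_max) > 0 &&
        (!length(domain_covariates) ||
           domain_check(sample_set[i, , drop = FALSE],
                        sample_set[train_max, , drop = FALSE],
                        domain_covariates))
      if (ok) test_idx <- c(test_idx, i) else n_discarded <- n_discarded + 1L
    }
    if (!length(test_idx)) stopf("no admissible test samples in repetition %d", rep_i)

    preds <- array(NA_real_,
                   c(length(model_specs), length(radii), length(test_idx)),
                   dimnames = list(names(model_specs), NULL, NULL))
    for (t in seq_along(test_idx)) {
      i <- test_idx[t]
      for (r_i in seq_along(radii)) {
        train <- which(D[i, ] > radii[r_i])
        if (!length(train)) {
          stopf("empty training set at radius %g km (test sample %d)",
                radii[r_i], i)
        }
        for (m in seq_along(model_specs)) {
          preds[m, r_i, t] <- fit_predict(model_specs[[m]],
                                          sample_set[train, , drop = FALSE],
                                          sample_set[i, , drop = FALSE])
        }
      }
    }
    obs <- sample_set$response[test_idx]
    for (m in seq_along(model_specs)) {
      for (r_i in seq_along(radii)) {
        p <- preds[m, r_i, ]
        per_rep[[length(per_rep) + 1L]] <- data.frame(
          model = names(model_specs)[m], rep = rep_i, radius_km = radii[r_i],
          r2 = suppressWarnings(r_squared(obs, p)), rmspe = rmspe(obs, p),
          n_test = length(test_idx))
      }
    }
  }

  per_rep <- do.call(rbind, per_rep)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep[, c("model", "radius_km")], drop = TRUE),
    function(d) {
      data.frame(model = d$model[1], radius_km = d$radius_km[1],
                 r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2),
                 rmspe_mean = mean(d$rmspe), rmspe_sd = stats::sd(d$rmspe),
                 n_test = min(d$n_test), n_reps = nrow(d))
    }))
  agg <- agg[order(agg$model, agg$radius_km), ]
  rownames(agg) <- NULL
  attr(agg, "n_discarded_by_safeguard") <- n_discarded
  attr(agg, "per_rep") <- per_rep
  class(agg) <- c("bloo_curve", "data.frame")
  agg
}
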