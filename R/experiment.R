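# Experiment orchestration: scenario -> filters -> variograms -> folds ->
# cross-validation -> report, with a reproducibility manifest.

#' Configure an end-to-end validation experiment
#'
#' @param scenario a [scenario_config()] or a path to a sample CSV
#'   (see [read_sample_set()]).
#' @param filters optional [filter_config()]; `NULL` skips filtering.
#' @param engineer_climate derive climate covariates from monthly column
#'   groups before modeling (see [engineer_climate()]).
#' @param model_specs list of `model_spec`s; at least one.
#' @param K random K-fold count.
#' @param H spatial clustering height (km).
#' @param radii,n_test,n_reps B-LOO parameters (see [bloo_cv()]); `radii =
#'   NULL` skips the B-LOO stage.
#' @param variogram_bin_width lag bin width (km) for diagnostics.
#' @param out_dir output directory (created); `NULL` keeps results in
#'   memory only.
#' @param seed master seed; per-stage seeds are derived as documented small
#'   offsets so toggling one stage leaves the others' draws unchanged.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(scenario, filters = NULL,
                              engineer_climate = FALSE,
                              model_specs = list(null_model_spec()),
                              K = 10, H = 150,
                              radii = seq(0, 150, by = 10), n_test = 100,
                              n_reps = 10, variogram_bin_width = 10,
                              out_dir = NULL, seed = 1L) {
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  if (!length(model_specs)) stopf("need at least one model spec")
  structure(list(scenario = scenario, filters = filters,
                 engineer_climate = engineer_climate,
                 model_specs = model_specs, K = K, H = H, radii = radii,
                 n_test = n_test, n_reps = n_reps,
                 variogram_bin_width = variogram_bin_width,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run a full validation experiment
#'
#' Executes scenario generation (or CSV ingestion), the filter chain,
#' covariate engineering, variogram diagnostics, the three CV strategies
#' (random K-fold, spatial K-fold, B-LOO) for every model spec, residual
#' variograms, and the skill-vs-distance report. All numeric outputs are
#' reproducible from the config alone; when `out_dir` is set, per-stage
#' CSVs and a JSON manifest are written.
#'
#' @param config an [experiment_config()].
#' @return a result bundle (list): `sample_set`, `filter_report`,
#'   `variogram`, `range_estimate`, `folds_random`, `folds_spatial`,
#'   `cv_random`, `cv_spatial` (lists keyed by model name),
#'   `residual_variograms`, `bloo`, `report`, `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  seed <- config$seed

  set <- stage("scenario", {
    if (inherits(config$scenario, "scenario_config")) {
      build_scenario(config$scenario)
    } else {
      read_sample_set(config$scenario)
    }
  })

  filter_report <- NULL
  if (!is.null(config$filters)) {
    filtered <- stage("filters", apply_filters(set, config$filters))
    set <- filtered$set
    filter_report <- filtered$report
  }
  if (isTRUE(config$engineer_climate)) {
    set <- stage("engineering", engineer_climate(set))
  }

  coords <- set[, c("x_km", "y_km")]
  vg <- stage("variogram",
              empirical_variogram(set$response, coords,
                                  bin_width = config$variogram_bin_width))
  rng <- stage("variogram", tryCatch(estimate_range(vg), error = function(e) NULL))

  folds_random <- stage("folds", random_kfold_split(nrow(set), config$K,
                                                    seed = seed + 1L))
  folds_spatial <- stage("folds", spatial_kfold_split(coords, config$H))

  cv_random <- list(); cv_spatial <- list(); res_vg <- list()
  for (m in config$model_specs) {
    cv_random[[m$name]] <- stage("cv_random", run_kfold_cv(m, set, folds_random))
    cv_spatial[[m$name]] <- stage("cv_spatial", run_kfold_cv(m, set, folds_spatial))
    res_vg[[m$name]] <- list(
      random = stage("residuals", residual_variogram(cv_random[[m$name]], coords,
                                                     config$variogram_bin_width)),
      spatial = stage("residuals", residual_variogram(cv_spatial[[m$name]], coords,
                                                      config$variogram_bin_width)))
  }

  bloo <- NULL
  if (!is.null(config$radii)) {
    bloo <- stage("bloo", bloo_cv(config$model_specs, set, radii = config$radii,
                                  n_test = config$n_test, n_reps = config$n_reps,
                                  seed = seed + 1000L))
  }

  null_name <- vapply(config$model_specs, function(m) m$type == "null", TRUE)
  report <- NULL
  if (!is.null(bloo)) {
    report <- stage("report", skill_vs_distance_report(
      bloo,
      spatial_r2 = vapply(cv_spatial, function(r) r$metrics$r2, 0),
      null_rmspe = if (any(null_name)) {
        cv_spatial[[which(null_name)[1]]]$metrics$rmspe
      } else {
        NA_real_
      }))
  }

  manifest <- list(
    seed = seed, n_samples = nrow(set), K_random = config$K, H = config$H,
    K_spatial = folds_spatial$K, radii = config$radii, n_test = config$n_test,
    n_reps = config$n_reps,
    models = lapply(config$model_specs, function(m) {
      m[c("name", "type", "predictors")]
    }),
    r_version = as.character(getRversion()),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- list(sample_set = set, filter_report = filter_report, variogram = vg,
              range_estimate = rng, folds_random = folds_random,
              folds_spatial = folds_spatial, cv_random = cv_random,
              cv_spatial = cv_spatial, residual_variograms = res_vg,
              bloo = bloo, report = report, manifest = manifest)

  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

# Fixed-precision numeric formatting keeps rerun outputs byte-stable.
fmt6 <- function(d) {
  for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- signif(d[[j]], 6)
  d
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_sample_set(result$sample_set, p("sample_set.csv"))
  write_variogram(result$variogram, p("variogram_response.csv"))
  if (!is.null(result$filter_report)) {
    write_filter_report(result$filter_report, p("filter_report.json"))
  }
  for (nm in names(result$cv_random)) {
    cv <- result$cv_random[[nm]]
    utils::write.csv(fmt6(data.frame(id = result$sample_set$id,
                                     observed = cv$observed,
                                     predicted = cv$predicted,
                                     fold = cv$fold_id)),
                     p(sprintf("cv_random_%s.csv", nm)), row.names = FALSE)
    write_variogram(result$residual_variograms[[nm]]$random,
                    p(sprintf("residuals_random_%s.csv", nm)))
    write_variogram(result$residual_variograms[[nm]]$spatial,
                    p(sprintf("residuals_spatial_%s.csv", nm)))
  }
  if (!is.null(result$bloo)) {
    utils::write.csv(fmt6(as.data.frame(result$bloo)), p("bloo_curve.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$report)) {
    utils::write.csv(fmt6(result$report), p("report.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Skill-versus-distance summary table
#'
#' Combines a B-LOO curve with the spatial K-fold reference: one row per
#' (model, radius) with the mean and SD of R2 and RMSPE over repetitions,
#' the spatial K-fold R2 of the same model as a horizontal reference, and
#' the null-model RMSPE as the no-skill error ceiling.
#'
#' @param bloo_curve a `bloo_curve` from [bloo_cv()].
#' @param spatial_r2 named numeric: spatial K-fold R2 per model.
#' @param null_rmspe scalar null-model RMSPE reference.
#' @return a data frame; round-trips losslessly through CSV at 6
#'   significant digits.
#' @export
skill_vs_distance_report <- function(bloo_curve, spatial_r2 = NULL,
                                     null_rmspe = NA_real_) {
  stopifnot(inherits(bloo_curve, "bloo_curve"))
  out <- as.data.frame(bloo_curve)
  out$spatial_kfold_r2 <- if (is.null(spatial_r2)) {
    NA_real_
  } else {
    unname(spatial_r2[out$model])
  }
  out$null_rmspe_ref <- null_rmspe
  out
}
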