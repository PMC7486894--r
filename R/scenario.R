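# Synthetic landscape scenarios: the generator that every downstream stage
# is exercised against.
#
# A scenario is a fully parameterized recipe for a point-sample dataset:
# a sampling layout, a set of covariate fields (independent Gaussian random
# fields), a linear predictor->response effect, a spatially structured
# response residual, and iid measurement noise. The response is
#
#   y(s) = sum_j beta_j * x_j(s) + e_spatial(s) + e_iid(s)
#
# With beta = 0 and a short-range e_spatial, covariates carry no information
# about the response, yet both live on the same landscape — the construction
# under which random cross-validation still reports predictive skill.

#' Specify one synthetic covariate field
#'
#' @param name column name in the generated sample table.
#' @param model covariance model (see [covariance_model()]).
#' @param range practical range (km).
#' @param sill partial sill.
#' @param nugget nugget variance. The default synthetic landscapes use a
#'   nugget fraction of 0 for covariates; the response field exposes its own.
#' @param mean constant field mean.
#' @return a `field_spec` list.
#' @export
field_spec <- function(name, model = "exponential", range = 300, sill = 1,
                       nugget = 0, mean = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("field name must be a non-empty string")
  }
  if (sill < 0 || nugget < 0) stopf("sill and nugget must be non-negative")
  if (model != "nugget" && sill > 0 && (!is.finite(range) || range <= 0)) {
    stopf("field '%s': non-nugget model requires range > 0", name)
  }
  structure(list(name = name, model = model, range = range, sill = sill,
                 nugget = nugget, mean = mean),
            class = "field_spec")
}

#' Parameterize a synthetic landscape scenario
#'
#' Defaults emulate the data structure of a 1-km tropical forest biomass
#' mapping campaign: a response with a ~120 km autocorrelation range,
#' predictors with ~250–500 km ranges, and inventory samples aggregated into
#' dense clusters with large unsampled swaths in between.
#'
#' @param extent rectangle `c(width_km, height_km)`.
#' @param n_samples total sample count (clustered layouts round up to a
#'   multiple of `n_clusters`, then truncate back to `n_samples`).
#' @param layout `"uniform"` or `"clustered"`.
#' @param n_clusters,cluster_radius clustered-layout parameters (km).
#' @param field_specs list of [field_spec()] covariate fields.
#' @param effect_coefficients numeric `beta`, one per covariate field;
#'   `beta = 0` gives a response carrying no covariate signal.
#' @param response_spatial [field_spec()]-like description (model, range,
#'   sill, nugget) of the spatially structured response residual. The default
#'   nugget fraction of the response field is 0.3 of its sill, a free choice
#'   exposed here.
#' @param iid_noise_sd standard deviation of iid response noise.
#' @param seed integer master seed; identical configs (including seed)
#'   regenerate identical sample sets.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(extent = c(1000, 1000),
                            n_samples = 2000,
                            layout = c("clustered", "uniform"),
                            n_clusters = 40,
                            cluster_radius = 20,
                            field_specs = default_covariate_fields(),
                            effect_coefficients = rep(0, length(field_specs)),
                            response_spatial = field_spec("response_spatial",
                              model = "exponential", range = 120, sill = 1,
                              nugget = 0.3),
                            iid_noise_sd = 0,
                            seed = 1L) {
  layout <- match.arg(layout)
  extent <- check_extent(extent)
  if (n_samples < 1) stopf("n_samples must be >= 1")
  if (inherits(field_specs, "field_spec")) field_specs <- list(field_specs)
  nm <- vapply(field_specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("covariate field names must be unique")
  if (length(effect_coefficients) != length(field_specs)) {
    stopf("effect_coefficients length (%d) must match field_specs length (%d)",
          length(effect_coefficients), length(field_specs))
  }
  if (iid_noise_sd < 0) stopf("iid_noise_sd must be >= 0")
  structure(list(extent = extent, n_samples = as.integer(n_samples),
                 layout = layout, n_clusters = as.integer(n_clusters),
                 cluster_radius = cluster_radius, field_specs = field_specs,
                 effect_coefficients = as.numeric(effect_coefficients),
                 response_spatial = response_spatial,
                 iid_noise_sd = iid_noise_sd, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default predictor fields: five long-range surfaces
#'
#' Five independent exponential fields with a 300 km practical range and unit
#' sill, standing in for remote-sensing and environmental covariates, whose
#' empirical ranges on the real landscape are on the order of 250–500 km.
#'
#' @param n_fields number of covariate fields.
#' @param range practical range (km).
#' @return list of [field_spec()].
#' @export
default_covariate_fields <- function(n_fields = 5, range = 300) {
  lapply(seq_len(n_fields), function(j) {
    field_spec(paste0("cov", j), "exponential", range = range, sill = 1)
  })
}

#' Generate a point-sample dataset from a scenario
#'
#' Draws the layout, simulates each covariate field and the response
#' components, and assembles the sample table. All randomness fans out from
#' `config$seed` through fixed per-stage offsets, so the result is
#' reproducible elementwise from the config alone.
#'
#' @param config a [scenario_config()].
#' @return a `data.frame` with columns `id`, `x_km`, `y_km`, `response`, and
#'   one column per covariate field; attribute `"provenance"` records the
#'   true generating parameters (beta, ranges, seeds) for parameter-recovery
#'   checks, and `"cluster"` the generating cluster index for clustered
#'   layouts.
#' @export
build_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed

  if (config$layout == "clustered") {
    ppc <- ceiling(config$n_samples / config$n_clusters)
    coords <- sample_clustered_layout(config$extent, config$n_clusters, ppc,
                                      config$cluster_radius, seed = seed + 1L)
    cluster <- attr(coords, "cluster")[seq_len(config$n_samples)]
    coords <- coords[seq_len(config$n_samples), , drop = FALSE]
  } else {
    coords <- sample_uniform_layout(config$extent, config$n_samples,
                                    seed = seed + 1L)
    cluster <- NULL
  }

  n <- nrow(coords)
  covs <- lapply(seq_along(config$field_specs), function(j) {
    fs <- config$field_specs[[j]]
    simulate_grf(coords, fs$model, fs$range, fs$sill, fs$nugget, fs$mean,
                 seed = seed + 10L + j)
  })
  names(covs) <- vapply(config$field_specs, `[[`, character(1), "name")

  rs <- config$response_spatial
  spatial <- simulate_grf(coords, rs$model, rs$range, rs$sill,
                          rs$nugget %||% 0, 0, seed = seed + 100L)
  noise <- if (config$iid_noise_sd > 0) {
    with_seed(seed + 101L, stats::rnorm(n, sd = config$iid_noise_sd))
  } else {
    numeric(n)
  }

  lin <- if (length(covs)) {
    drop(do.call(cbind, covs) %*% config$effect_coefficients)
  } else {
    numeric(n)
  }
  response <- lin + spatial + noise

  out <- data.frame(id = seq_len(n), x_km = coords[, 1], y_km = coords[, 2],
                    response = response)
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]

  attr(out, "cluster") <- cluster
  attr(out, "provenance") <- list(
    beta = config$effect_coefficients,
    covariate_names = names(covs),
    covariate_ranges = vapply(config$field_specs, `[[`, numeric(1), "range"),
    response_range = rs$range, response_sill = rs$sill,
    response_nugget = rs$nugget %||% 0,
    iid_noise_sd = config$iid_noise_sd,
    layout = config$layout, extent = config$extent, seed = seed)
  out
}

#' Column names of the covariates in a sample table
#'
#' Everything that is not an identifier, a coordinate, the response, or a
#' recognized QC column is treated as a covariate.
#'
#' @param set a sample `data.frame`.
#' @return character vector of covariate column names.
#' @export
covariate_names <- function(set) {
  reserved <- c("id", "x_km", "y_km", "response",
                "plot_count", "forest_cover_pct", "forest_loss_pct", "fire_pct")
  setdiff(names(set), reserved)
}

#' Write / read a sample table as CSV with a JSON provenance sidecar
#'
#' @param set sample `data.frame` from [build_scenario()] or compatible.
#' @param path CSV path; provenance (if present) goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sample_set <- function(set, path) {
  utils::write.csv(set, path, row.names = FALSE)
  prov <- attr(set, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_sample_set
#' @param allow_duplicate_coords keep duplicated coordinate pairs; otherwise
#'   reading a table with duplicates is an error.
#' @export
read_sample_set <- function(path, allow_duplicate_coords = FALSE) {
  set <- utils::read.csv(path)
  required <- c("id", "x_km", "y_km", "response")
  missing <- setdiff(required, names(set))
  if (length(missing)) stopf("sample CSV lacks columns: %s",
                             paste(missing, collapse = ", "))
  if (anyDuplicated(set$id)) stopf("sample ids must be unique")
  if (!all(is.finite(set$x_km)) || !all(is.finite(set$y_km))) {
    stopf("coordinates must be finite")
  }
  if (!allow_duplicate_coords && anyDuplicated(set[, c("x_km", "y_km")])) {
    stopf("duplicated coordinate pairs (pass allow_duplicate_coords = TRUE to keep)")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(set, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  set
}
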