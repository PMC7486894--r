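# Canonical demonstration scenarios.
#
# Two fixed study conditions exercised by the analysis scripts and the
# acceptance checks:
#
# * spurious-skill: the response is a short-range (120 km) field entirely
#   unrelated to the five long-range (300 km) covariates (beta = 0), plus
#   10% iid noise, sampled in 40 dense clusters of 50 over a 1000 x 1000 km
#   region. Any skill a covariate model shows here under random CV is
#   spatial leakage by construction.
#
# * genuine-skill: the response is a linear combination of three long-range
#   covariates driving ~75% of its variance, with no spatially structured
#   residual. A validation scheme must not destroy this real skill.

#' Spurious-skill study conditions
#'
#' Clustered sampling (40 clusters x 50 samples, 20 km cluster scale) on a
#' 1000 x 1000 km extent; five exponential covariate fields with a 300 km
#' practical range and unit sill; response an independent exponential field
#' with a 120 km range and unit sill plus iid noise contributing 10% of the
#' total response variance (`sd = sqrt(1/9)`); all effect coefficients zero.
#'
#' @param seed integer master seed.
#' @param n_samples total samples (default 2000).
#' @return a [scenario_config()].
#' @export
spurious_skill_config <- function(seed = 1L, n_samples = 2000) {
  scenario_config(
    extent = c(1000, 1000), n_samples = n_samples, layout = "clustered",
    n_clusters = 40, cluster_radius = 20,
    field_specs = default_covariate_fields(n_fields = 5, range = 300),
    effect_coefficients = rep(0, 5),
    response_spatial = field_spec("response_spatial", "exponential",
                                  range = 120, sill = 1, nugget = 0),
    iid_noise_sd = sqrt(1 / 9), seed = seed)
}

#' Genuine-skill control conditions
#'
#' Uniformly sampled landscape in which three long-range covariates with
#' unit coefficients drive 75% of the response variance
#' (`iid_noise_sd = 1`, no spatially structured residual), so a spatially
#' blocked validation should still report substantial skill.
#'
#' @param seed integer master seed.
#' @param n_samples total samples (default 1000).
#' @return a [scenario_config()].
#' @export
genuine_skill_config <- function(seed = 1L, n_samples = 1000) {
  scenario_config(
    extent = c(1000, 1000), n_samples = n_samples, layout = "uniform",
    field_specs = default_covariate_fields(n_fields = 3, range = 300),
    effect_coefficients = c(1, 1, 1),
    response_spatial = field_spec("response_spatial", "nugget",
                                  range = NA, sill = 0, nugget = 0),
    iid_noise_sd = 1, seed = seed)
}
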