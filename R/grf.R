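# Gaussian random field simulation on point supports.
#
# Fields are simulated by dense covariance factorization (Cholesky with a
# small diagonal jitter), which is exact and fast at the scale this package
# targets (a few thousand points per field). Larger problems should be
# tackled with spectral or nearest-neighbour approximations, which are
# deliberately out of scope here.

# Hard cap on n for dense factorization; an 8000 x 8000 double matrix is
# ~0.5 GB and its Cholesky is still sub-minute, beyond that memory becomes
# the binding constraint.
GRF_N_CAP <- 8000L

#' Stationary isotropic covariance function
#'
#' Evaluates the covariance `C(h)` of the supported variogram models at lag
#' distance `h` (km). The exponential model uses the practical-range
#' parameterization `C(h) = sill * exp(-3 h / range)`, so that `range` is the
#' distance at which correlation has decayed to 5% — the distance a
#' practitioner reads off an empirical semivariogram as "the range of
#' autocorrelation". The spherical model uses the standard closed form and
#' reaches exactly zero at `h = range`. The pure-nugget model has covariance
#' `sill` at `h = 0` and zero elsewhere.
#'
#' @param h numeric vector of lag distances (km), non-negative.
#' @param model one of `"exponential"`, `"spherical"`, `"nugget"`.
#' @param range practical range (km); required positive for non-nugget models.
#' @param sill partial sill (variance of the structured component).
#' @return numeric vector of covariances, same length as `h`.
#' @export
covariance_model <- function(h, model = c("exponential", "spherical", "nugget"),
                             range = NA_real_, sill = 1) {
  model <- match.arg(model)
  if (model != "nugget" && (!is.finite(range) || range <= 0)) {
    stopf("model '%s' requires a positive range (got %s)", model, format(range))
  }
  switch(model,
    exponential = sill * exp(-3 * h / range),
    spherical = ifelse(h < range,
      sill * (1 - 1.5 * h / range + 0.5 * (h / range)^3), 0),
    nugget = ifelse(h == 0, sill, 0)
  )
}

#' Theoretical semivariance
#'
#' The semivariogram implied by [covariance_model()] plus a nugget effect:
#' `gamma(h) = nugget + sill - C(h)` for `h > 0`, and `gamma(0) = 0`.
#'
#' @inheritParams covariance_model
#' @param nugget nugget variance (discontinuity at the origin).
#' @return numeric vector of semivariances.
#' @export
theoretical_semivariance <- function(h, model = c("exponential", "spherical", "nugget"),
                                     range = NA_real_, sill = 1, nugget = 0) {
  model <- match.arg(model)
  g <- nugget + sill - covariance_model(h, model, range, sill)
  g[h == 0] <- 0
  g
}

#' Simulate a Gaussian random field at point locations
#'
#' Draws one realization of a stationary, isotropic Gaussian process with the
#' given covariance model at arbitrary point locations, by Cholesky
#' factorization of the dense covariance matrix. A small diagonal jitter is
#' added (and escalated) if the factorization fails, e.g. with duplicated
#' coordinates and no nugget.
#'
#' @param coords two-column matrix or data frame of planar coordinates (km).
#' @param model covariance model, see [covariance_model()].
#' @param range practical range (km).
#' @param sill partial sill (variance of the spatially structured component).
#' @param nugget nugget variance, added as spatially uncorrelated noise.
#' @param mean constant process mean.
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @return numeric vector of field values, one per coordinate row.
#' @examples
#' xy <- cbind(runif(50, 0, 100), runif(50, 0, 100))
#' z <- simulate_grf(xy, "exponential", range = 40, sill = 1, seed = 1)
#' @export
simulate_grf <- function(coords, model = c("exponential", "spherical", "nugget"),
                         range = NA_real_, sill = 1, nugget = 0, mean = 0,
                         seed = NULL) {
  model <- match.arg(model)
  coords <- as_coords(coords)
  n <- nrow(coords)
  if (sill < 0 || nugget < 0) stopf("sill and nugget must be non-negative")
  if (model != "nugget" && sill > 0 && (!is.finite(range) || range <= 0)) {
    stopf("model '%s' requires a positive range", model)
  }

  if (sill + nugget == 0) {
    return(rep(mean, n))
  }

  # A nugget-model sill is indistinguishable from nugget variance: both are
  # iid white noise, so no factorization is needed.
  white_var <- nugget + if (model == "nugget") sill else 0
  structured <- model != "nugget" && sill > 0

  with_seed(seed, {
    z <- numeric(n)
    if (structured) {
      # the cap only binds when a dense factorization is actually needed
      if (n > GRF_N_CAP) {
        stopf("n = %d exceeds the dense-factorization cap of %d points",
              n, GRF_N_CAP)
      }
      d <- as.matrix(stats::dist(coords))
      sigma <- covariance_model(d, model, range, sill)
      diag(sigma) <- sill
      jitter <- 1e-10 * sill
      l <- NULL
      for (i in 1:7) {
        l <- tryCatch(chol(sigma + diag(jitter, n)), error = function(e) NULL)
        if (!is.null(l)) break
        jitter <- jitter * 100
      }
      if (is.null(l)) {
        stopf("covariance factorization failed even after diagonal jitter up to %g", jitter)
      }
      z <- drop(crossprod(l, stats::rnorm(n)))
    }
    if (white_var > 0) {
      z <- z + stats::rnorm(n, sd = sqrt(white_var))
    }
    mean + z
  })
}
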