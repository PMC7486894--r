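# Derived climate and spectral covariates.
#
# These are the application-specific layers computed from monthly
# climatologies (12-month P, PET, T, SR, WP vectors) and from composited
# surface reflectance: annual water availability, monthly water deficit,
# dry-season length/severity statistics, the maximal climate water deficit
# (MCWD), seasonality statistics, and the EVI2 and NDII vegetation indices.
# Dry seasons are treated circularly across the Dec->Jan boundary, because
# equatorial bimodal climates straddle the calendar year.

check_monthly <- function(x, name, non_negative = FALSE) {
  if (length(x) != 12L || !all(is.finite(x))) {
    stopf("%s must be 12 finite monthly values", name)
  }
  if (non_negative && any(x < 0)) stopf("%s must be non-negative", name)
  as.numeric(x)
}

#' Annual water availability
#'
#' The ratio of cumulative annual precipitation to cumulative potential
#' evapotranspiration, `WA = sum(P) / sum(PET)` (unitless; values below 1
#' indicate an annual water deficit).
#'
#' @param P monthly precipitation, 12 values (mm).
#' @param PET monthly potential evapotranspiration, 12 values (mm).
#' @return scalar WA.
#' @export
water_availability <- function(P, PET) {
  P <- check_monthly(P, "P", TRUE); PET <- check_monthly(PET, "PET", TRUE)
  if (sum(PET) == 0) stopf("sum(PET) must be > 0")
  sum(P) / sum(PET)
}

#' Monthly water deficit
#'
#' Elementwise `P - PET` (mm); negative values mark dry-season months.
#'
#' @inheritParams water_availability
#' @return 12 monthly deficits (mm).
#' @export
monthly_deficit <- function(P, PET) {
  P <- check_monthly(P, "P", TRUE); PET <- check_monthly(PET, "PET", TRUE)
  P - PET
}

# Circular runs of TRUE in a 12-month logical vector. Returns a list of
# integer month-index vectors, one per run.
circular_runs <- function(dry) {
  n <- length(dry)
  if (all(dry)) return(list(seq_len(n)))
  if (!any(dry)) return(list())
  # rotate so position 1 is wet, making runs contiguous
  start <- which(!dry)[1]
  rot <- ((seq_len(n) + start - 2L) %% n) + 1L     # rot[i] = original index
  dr <- dry[rot]
  r <- rle(dr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) runs[[length(runs) + 1L]] <- rot[starts[k]:ends[k]]
  }
  runs
}

#' Dry-season statistics from the monthly water deficit
#'
#' Dry months are those with a negative deficit. Reports the cumulative
#' dry-season length (count of all dry months) and the longest dry-season
#' length (longest circular run of consecutive dry months, wrapping
#' Dec->Jan), with the corresponding severities as positive magnitudes of
#' the summed deficits. Ties between equal-length runs are broken by the
#' greater severity. When monthly solar radiation (`SR`) or water vapor
#' pressure (`WP`) are supplied, their mean and max over the longest run are
#' reported too.
#'
#' @param deficit 12 monthly water deficits (mm), e.g. [monthly_deficit()].
#' @param SR,WP optional 12-month solar radiation / water vapor pressure.
#' @return list with `DS_long_length`, `DS_cumu_length` (months),
#'   `DS_long_sever`, `DS_cumu_sever` (mm, >= 0), and, when available,
#'   `SolRad_DS_m`, `SolRad_DS_max`, `Vapor_DS_m`, `Vapor_DS_max`.
#' @export
dry_season_stats <- function(deficit, SR = NULL, WP = NULL) {
  deficit <- check_monthly(deficit, "deficit")
  dry <- deficit < 0
  runs <- circular_runs(dry)
  out <- list(DS_long_length = 0L, DS_cumu_length = sum(dry),
              DS_long_sever = 0, DS_cumu_sever = -sum(deficit[dry]),
              SolRad_DS_m = NA_real_, SolRad_DS_max = NA_real_,
              Vapor_DS_m = NA_real_, Vapor_DS_max = NA_real_)
  if (length(runs)) {
    lens <- lengths(runs)
    sever <- vapply(runs, function(m) -sum(deficit[m]), 0)
    best <- which(lens == max(lens))
    best <- best[which.max(sever[best])]      # tie-break: greater severity
    longest <- runs[[best]]
    out$DS_long_length <- length(longest)
    out$DS_long_sever <- sever[best]
    if (!is.null(SR)) {
      SR <- check_monthly(SR, "SR")
      out$SolRad_DS_m <- mean(SR[longest]); out$SolRad_DS_max <- max(SR[longest])
    }
    if (!is.null(WP)) {
      WP <- check_monthly(WP, "WP")
      out$Vapor_DS_m <- mean(WP[longest]); out$Vapor_DS_max <- max(WP[longest])
    }
  }
  out
}

#' Maximal climate water deficit (MCWD)
#'
#' Iterates the running water deficit `WD_n = min(0, WD_{n-1} + P_n - PET_n)`
#' circularly over the 12 months until the monthly values stabilize (two
#' passes suffice whenever some month replenishes the deficit), then returns
#' the most negative value of the final cycle. By construction `CWD <= 0`,
#' with 0 meaning no month ever runs a deficit. The circular iteration makes
#' the result independent of where the dry season falls relative to the
#' calendar start. A perennial-deficit climatology (the running deficit
#' never returns to 0, so the circular recursion has no fixed point) falls
#' back to the single-cycle deficit from a zero start — the bounded,
#' climatologically meaningful annual value.
#'
#' @inheritParams water_availability
#' @return scalar CWD (mm, `<= 0`, bounded below by `-sum(PET)`).
#' @export
mcwd <- function(P, PET) {
  P <- check_monthly(P, "P", TRUE); PET <- check_monthly(PET, "PET", TRUE)
  delta <- P - PET
  one_pass <- function(wd) {
    cur <- numeric(12)
    for (m in 1:12) {
      wd <- min(0, wd + delta[m])
      cur[m] <- wd
    }
    cur
  }
  first <- one_pass(0)
  prev <- first
  for (pass in 1:23) {
    cur <- one_pass(prev[12])
    if (identical(cur, prev)) {
      return(min(0, cur))
    }
    prev <- cur
  }
  min(0, first)
}

#' Seasonality of a monthly climatology
#'
#' Population standard deviation over the 12 months (`mode = "sd"`), or the
#' coefficient of variation `100 * SD / mean` (`mode = "cv"`). The 12 months
#' are the complete climatological population, hence the population (not
#' sample) SD. Temperature seasonality is conventionally reported as
#' `SD * 100`; see [temperature_seasonality()].
#'
#' @param x 12 monthly values.
#' @param mode `"sd"` or `"cv"`.
#' @return scalar statistic.
#' @export
seasonality <- function(x, mode = c("sd", "cv")) {
  mode <- match.arg(mode)
  x <- check_monthly(x, "x")
  s <- sqrt(mean((x - mean(x))^2))
  if (mode == "sd") return(s)
  if (mean(x) == 0) stopf("coefficient of variation undefined for zero mean")
  100 * s / mean(x)
}

#' @rdname seasonality
#' @param T 12 monthly mean temperatures (degrees C).
#' @export
temperature_seasonality <- function(T) 100 * seasonality(T, "sd")

#' Two-band enhanced vegetation index (EVI2)
#'
#' `EVI2 = 2.5 * (NIR - RED) / (NIR + 2.4 * RED + 1)` on reflectances.
#'
#' @param red,nir surface reflectance (unitless, typically in `[0, 1]`).
#' @return EVI2 (unitless).
#' @export
evi2 <- function(red, nir) {
  if (!all(is.finite(red)) || !all(is.finite(nir))) stopf("reflectances must be finite")
  den <- nir + 2.4 * red + 1
  if (any(den == 0)) stopf("EVI2 denominator is zero")
  2.5 * (nir - red) / den
}

#' Normalized difference infrared index (NDII)
#'
#' `NDII = (NIR - SWIR) / (NIR + SWIR)`; the shortwave-infrared band is
#' SWIR1 by convention here, configurable by passing another band.
#'
#' @param nir,swir surface reflectance (unitless).
#' @return NDII (unitless, in `[-1, 1]` for non-negative reflectances).
#' @export
ndii <- function(nir, swir) {
  if (!all(is.finite(nir)) || !all(is.finite(swir))) stopf("reflectances must be finite")
  den <- nir + swir
  if (any(den == 0)) stopf("NDII denominator is zero")
  (nir - swir) / den
}

#' Full set of derived climate layers for one location
#'
#' Convenience wrapper computing every derived climate covariate from the
#' monthly climatology of a single pixel.
#'
#' @param P,PET,T,SR,WP 12-month climatologies (mm, mm, degrees C,
#'   kJ m-2 day-1, kPa); `T`, `SR`, `WP` optional.
#' @return named list: `WA`, `monthly_deficit`, dry-season statistics,
#'   `CWD`, `T_seaso`, `Prec_seaso`, `Vapor_sd`, `SolRad_sd`.
#' @export
derive_climate <- function(P, PET, T = NULL, SR = NULL, WP = NULL) {
  deficit <- monthly_deficit(P, PET)
  out <- c(list(WA = water_availability(P, PET), monthly_deficit = deficit),
           dry_season_stats(deficit, SR = SR, WP = WP),
           list(CWD = mcwd(P, PET),
                Prec_seaso = seasonality(P, "cv"),
                T_seaso = if (!is.null(T)) temperature_seasonality(T) else NA_real_,
                SolRad_sd = if (!is.null(SR)) seasonality(SR, "sd") else NA_real_,
                Vapor_sd = if (!is.null(WP)) seasonality(WP, "sd") else NA_real_))
  out
}

#' Append derived climate columns to a sample table
#'
#' Expects monthly climatologies as 12-column groups named `P01..P12`,
#' `PET01..PET12` and optionally `T01..T12`, `SR01..SR12`, `WP01..WP12`, as
#' produced when point-sampling monthly rasters. Appends the scalar derived
#' layers as new columns (monthly deficits are not appended).
#'
#' @param set sample `data.frame` with monthly column groups.
#' @return `set` with derived climate columns appended.
#' @export
engineer_climate <- function(set) {
  grp <- function(prefix) {
    cols <- sprintf("%s%02d", prefix, 1:12)
    if (all(cols %in% names(set))) as.matrix(set[, cols]) else NULL
  }
  P <- grp("P"); PET <- grp("PET")
  if (is.null(P) || is.null(PET)) stopf("need P01..P12 and PET01..PET12 columns")
  Tm <- grp("T"); SR <- grp("SR"); WP <- grp("WP")
  scalars <- c("WA", "DS_long_length", "DS_cumu_length", "DS_long_sever",
               "DS_cumu_sever", "SolRad_DS_m", "SolRad_DS_max", "Vapor_DS_m",
               "Vapor_DS_max", "CWD", "Prec_seaso", "T_seaso", "SolRad_sd",
               "Vapor_sd")
  rows <- lapply(seq_len(nrow(set)), function(i) {
    d <- derive_climate(P[i, ], PET[i, ],
                        T = if (!is.null(Tm)) Tm[i, ],
                        SR = if (!is.null(SR)) SR[i, ],
                        WP = if (!is.null(WP)) WP[i, ])
    unlist(d[scalars])
  })
  derived <- do.call(rbind, rows)
  for (nm in scalars) set[[nm]] <- derived[, nm]
  set
}
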