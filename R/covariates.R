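## covariates: per-microplot / per-crop-period explanatory variables for
## the driver analysis (WFPS, texture ratio, transect slope, period means).

#' Water-filled pore space
#'
#' `WFPS (%) = 100 * theta_v / (1 - BD / 2.65)`, with bulk density `BD` in
#' g cm^-3 and particle density fixed at 2.65 g cm^-3. Volumetric water
#' content is accepted as a fraction; inputs above 1 are interpreted as
#' percent and divided by 100 with a warning. Values above 100 % (a
#' supersaturated logger reading) are clipped to 100 with a warning.
#'
#' @param theta_v Volumetric water content, fraction of bulk volume
#'   (vectorised).
#' @param bd Bulk density, g cm^-3, in (0, 2.65).
#' @return WFPS in percent, in [0, 100].
#' @examples
#' wfps(0.30, 1.70)  # ~83.68 %
#' @export
wfps <- function(theta_v, bd) {
  if (any(!is.finite(theta_v)) || any(!is.finite(bd))) {
    stop("theta_v and bd must be finite")
  }
  if (any(bd >= .PARTICLE_DENSITY) || any(bd <= 0)) {
    stop("bulk density must lie in (0, 2.65) g cm^-3")
  }
  if (any(theta_v > 1)) {
    warning("theta_v > 1 interpreted as percent and divided by 100")
    theta_v <- ifelse(theta_v > 1, theta_v / 100, theta_v)
  }
  if (any(theta_v < 0)) stop("theta_v must be >= 0")
  out <- 100 * theta_v / (1 - bd / .PARTICLE_DENSITY)
  if (any(out > 100)) {
    warning("WFPS above 100 % clipped (supersaturated reading)")
    out <- pmin(out, 100)
  }
  out
}

#' Silt-plus-clay to sand ratio
#'
#' One-number texture summary `(silt + clay) / sand`; fine-textured soils
#' score high, pure sand scores 0.
#'
#' @param sand,silt,clay Texture components in percent (vectorised);
#'   `sand` must be positive.
#' @return The SC:S ratio (dimensionless, >= 0).
#' @examples
#' scs_ratio(83.3, 11.8, 4.9)  # ~0.20
#' @export
scs_ratio <- function(sand, silt, clay) {
  if (any(sand <= 0)) stop("sand content must be positive")
  if (any(silt < 0) || any(clay < 0)) stop("texture components must be >= 0")
  (silt + clay) / sand
}

#' Transect slope in percent
#'
#' `100 * (highest - lowest elevation) / distance between those two
#' positions` along a transect.
#'
#' @param elevations Elevations, m a.s.l. (>= 2 points).
#' @param positions Along-transect positions, m, same length.
#' @return Slope in percent (0 for a flat transect).
#' @export
slope_percent <- function(elevations, positions) {
  stopifnot(length(elevations) == length(positions),
            length(elevations) >= 2)
  i_max <- which.max(elevations)
  i_min <- which.min(elevations)
  rise <- elevations[i_max] - elevations[i_min]
  if (rise == 0) return(0)
  run <- abs(positions[i_max] - positions[i_min])
  if (run == 0) stop("extreme elevations at coincident positions")
  100 * rise / run
}

#' Aggregate covariates over one crop period
#'
#' Unweighted means of daily logger values over period days (sub-daily
#' records are first averaged day-wise, so uneven logging density cannot
#' bias the period mean), the period N fertilizer sum from the event
#' calendar, and the transect slope from the profile table. Records with
#' logger coverage below `min_coverage` of period days are flagged, not
#' dropped.
#'
#' @param loggers Logger series for one microplot: columns `date` (or
#'   `datetime`), `theta_v`, `air_temp_c`, optionally `soil_temp_c`.
#' @param weather Optional daily weather (`date`, `precip_mm`); adds the
#'   period precipitation sum.
#' @param events Event calendar (fertilizer sums use `mineral_fert` and
#'   `organic_fert` rows inside the period).
#' @param profile One-row soil profile for the microplot (`sand`, `silt`,
#'   `clay`, `bd`, `tn`; slope uses `elevation`/`position_m` of the whole
#'   patch if supplied with more rows).
#' @param period_start,period_end Crop period boundaries.
#' @param co2_daily Optional daily CO2 flux values for the period
#'   (mg CO2-C m^-2 h^-1), averaged into `mean_co2_flux`.
#' @param min_coverage Minimum fraction of period days with logger data
#'   (default 0.5).
#' @return One-row data frame: `mean_theta_v`, `mean_wfps`,
#'   `mean_air_temp_c`, `mean_soil_temp_c`, `scs_ratio`, `slope_pct`,
#'   `n_fertilizer`, `precip_sum`, `mean_co2_flux`, `coverage`,
#'   `coverage_ok`.
#' @export
aggregate_period_covariates <- function(loggers, events, profile,
                                        period_start, period_end,
                                        weather = NULL, co2_daily = NULL,
                                        min_coverage = 0.5) {
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  day <- if ("date" %in% names(loggers)) {
    as.Date(loggers$date)
  } else {
    as.Date(loggers$datetime)
  }
  inp <- day >= period_start & day <= period_end
  loggers <- loggers[inp, , drop = FALSE]
  day <- day[inp]
  n_days <- as.numeric(period_end - period_start) + 1
  coverage <- length(unique(day)) / n_days
  daily_mean <- function(x) {
    if (is.null(x)) return(NA_real_)
    mean(tapply(x, day, mean, na.rm = TRUE), na.rm = TRUE)
  }
  mtheta <- daily_mean(loggers$theta_v)
  bd1 <- profile$bd[1]
  fert <- events[events$kind %in% c("mineral_fert", "organic_fert") &
                   as.Date(events$date) >= period_start &
                   as.Date(events$date) <= period_end, , drop = FALSE]
  slope <- if (nrow(profile) >= 2 && "elevation" %in% names(profile)) {
    slope_percent(profile$elevation, profile$position_m)
  } else {
    NA_real_
  }
  data.frame(
    mean_theta_v = mtheta,
    mean_wfps = if (is.na(mtheta)) NA_real_ else wfps(mtheta, bd1),
    mean_air_temp_c = daily_mean(loggers$air_temp_c),
    mean_soil_temp_c = daily_mean(loggers$soil_temp_c),
    scs_ratio = scs_ratio(profile$sand[1], profile$silt[1],
                          profile$clay[1]),
    slope_pct = slope,
    n_fertilizer = sum(fert$magnitude),
    precip_sum = if (is.null(weather)) NA_real_ else {
      wd <- as.Date(weather$date)
      sum(weather$precip_mm[wd >= period_start & wd <= period_end])
    },
    mean_co2_flux = if (is.null(co2_daily)) NA_real_ else
      mean(co2_daily, na.rm = TRUE),
    coverage = coverage,
    coverage_ok = coverage >= min_coverage)
}
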