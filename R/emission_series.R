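## emission_series: campaign fluxes -> daily series -> cumulative crop
## emissions -> hot-moment attribution.
##
## Campaign fluxes are interpolated linearly between measurement dates to a
## daily grid spanning the crop period (constant extrapolation beyond the
## first/last campaign), integrated with the trapezoidal rule, and split
## additively into hot-moment and background shares using event windows
## (14 d after fertilization, 7 d after heavy rain > 20 mm d^-1, unioned).

## ug N2O-N m^-2 h^-1 sustained for one day -> g N2O-N ha^-1 d^-1:
## x 24 h d^-1 x 1e4 m2 ha^-1 x 1e-6 g ug^-1 = x 0.24
.UGM2H_TO_GHA_D <- 0.24

## trapezoidal integral of a daily series, in value-days
.trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2)

.check_daily <- function(series) {
  stopifnot(all(c("date", "flux") %in% names(series)))
  if (nrow(series) < 2) stop("daily series needs at least 2 days")
  d <- diff(as.numeric(series$date))
  if (any(d != 1)) stop("daily series has gaps or is unsorted")
  if (any(!is.finite(series$flux))) stop("daily series has missing fluxes")
  invisible(series)
}

#' Interpolate campaign fluxes to a daily series
#'
#' Linear interpolation between consecutive campaign dates on a daily grid
#' covering the crop period; before the first and after the last campaign
#' the nearest measured value is carried constant. The interpolated value
#' at a campaign date equals the measured flux exactly. Multiple valid
#' fluxes on one date (e.g. repeated closures) are averaged first.
#'
#' @param dates Campaign dates (`Date` or coercible).
#' @param fluxes Measured fluxes (ug N2O-N m^-2 h^-1); `NA`s are dropped.
#' @param period_start,period_end Crop period boundaries (`Date`).
#' @return Data frame with `date` (daily grid, inclusive) and `flux`.
#' @export
interpolate_fluxes <- function(dates, fluxes, period_start, period_end) {
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  if (period_end <= period_start) stop("period_end must follow period_start")
  dates <- as.Date(dates)
  ok <- is.finite(fluxes) & !is.na(dates)
  if (!any(ok)) {
    stop(errorCondition("no valid fluxes in or around the period",
                        class = c("patchflux_empty_series", "error")))
  }
  dates <- dates[ok]
  fluxes <- fluxes[ok]
  agg <- tapply(fluxes, as.numeric(dates), mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  grid <- seq(period_start, period_end, by = "day")
  flux <- if (length(x) == 1) {
    rep(y, length(grid))
  } else {
    approx(x, y, xout = as.numeric(grid), method = "linear", rule = 2)$y
  }
  data.frame(date = grid, flux = flux)
}

#' Cumulative crop-period emission from a daily flux series
#'
#' Trapezoidal integration of the daily series over the crop period,
#' converted from ug N2O-N m^-2 h^-1 to g N2O-N ha^-1 per period
#' (x 24 h d^-1 x 1e4 m2 ha^-1 x 1e-6 g ug^-1).
#'
#' @param series Daily series as returned by [interpolate_fluxes()]
#'   (complete daily grid, no gaps).
#' @return Cumulative emission, g N2O-N ha^-1 period^-1.
#' @export
cumulative_emission <- function(series) {
  .check_daily(series)
  .trapz(series$flux) * .UGM2H_TO_GHA_D
}

#' Validate an event calendar
#'
#' @param calendar Data frame with columns `date`, `kind` (one of
#'   `"mineral_fert"`, `"organic_fert"`, `"rain"`) and `magnitude`
#'   (kg N ha^-1 for fertilization, mm d^-1 for rain).
#' @param rain_threshold Heavy-rain trigger, mm d^-1 (default 20); rain
#'   events must exceed it.
#' @return The calendar, invisibly; errors on violations.
#' @export
validate_event_calendar <- function(calendar, rain_threshold = 20) {
  stopifnot(all(c("date", "kind", "magnitude") %in% names(calendar)))
  if (nrow(calendar) == 0) return(invisible(calendar))
  if (!all(calendar$kind %in% c("mineral_fert", "organic_fert", "rain"))) {
    stop("unknown event kind")
  }
  if (any(is.na(as.Date(calendar$date)))) stop("invalid event dates")
  if (any(calendar$magnitude < 0)) stop("event magnitudes must be >= 0")
  rain <- calendar$kind == "rain"
  if (any(rain & calendar$magnitude <= rain_threshold)) {
    stop("rain events must exceed ", rain_threshold, " mm d^-1")
  }
  fert <- calendar$kind %in% c("mineral_fert", "organic_fert")
  if (any(fert & calendar$magnitude <= 0)) {
    stop("fertilization events must carry a positive N amount")
  }
  invisible(calendar)
}

#' Hot-moment window mask for a crop period
#'
#' Marks days inside the union of post-event windows: `[event, event + 13]`
#' for fertilization and `[event, event + 6]` for heavy rain
#' (> `rain_threshold` mm d^-1). Windows are inclusive of the event day and
#' overlaps are counted once.
#'
#' @param calendar Event calendar (see [validate_event_calendar()]).
#' @param period_start,period_end Crop period boundaries (`Date`).
#' @param fert_window,rain_window Window lengths in days (defaults 14, 7).
#' @param rain_threshold Heavy-rain trigger, mm d^-1 (default 20).
#' @return Data frame with `date` (daily grid) and logical `hot`.
#' @export
identify_hot_moments <- function(calendar, period_start, period_end,
                                 fert_window = 14, rain_window = 7,
                                 rain_threshold = 20) {
  validate_event_calendar(calendar, rain_threshold)
  grid <- seq(as.Date(period_start), as.Date(period_end), by = "day")
  hot <- rep(FALSE, length(grid))
  if (nrow(calendar) > 0) {
    for (j in seq_len(nrow(calendar))) {
      e <- as.Date(calendar$date[j])
      len <- if (calendar$kind[j] == "rain") rain_window else fert_window
      hot <- hot | (grid >= e & grid <= e + (len - 1))
    }
  }
  data.frame(date = grid, hot = hot)
}

#' Partition cumulative emission into hot-moment and background shares
#'
#' Integrates the daily series with the same trapezoidal rule as
#' [cumulative_emission()], splitting each one-day interval between the hot
#' and background budgets by the fraction of its endpoints inside the
#' window mask (0, 1/2 or 1). The two parts therefore sum to the total
#' exactly.
#'
#' @param series Daily flux series (see [interpolate_fluxes()]).
#' @param mask Window mask aligned to the same daily grid (see
#'   [identify_hot_moments()]).
#' @return One-row data frame: `hot_emission`, `background_emission`,
#'   `total_emission` (g N2O-N ha^-1), `share_pct` (0-100, `NA` with
#'   `share_defined = FALSE` when the total is not positive), and
#'   `hot_days`.
#' @export
hot_moment_share <- function(series, mask) {
  .check_daily(series)
  if (nrow(series) != nrow(mask) ||
      any(as.Date(series$date) != as.Date(mask$date))) {
    stop("series and mask must share the same daily grid")
  }
  f <- series$flux
  m <- as.numeric(mask$hot)
  ci <- (f[-1] + f[-length(f)]) / 2 * .UGM2H_TO_GHA_D
  wi <- (m[-1] + m[-length(m)]) / 2
  hot <- sum(ci * wi)
  bg <- sum(ci * (1 - wi))
  tot <- hot + bg          # additive by construction, exact partition
  share <- if (tot > 0) 100 * hot / tot else NA_real_
  data.frame(hot_emission = hot, background_emission = bg,
             total_emission = tot, share_pct = share,
             share_defined = tot > 0, hot_days = sum(mask$hot))
}

#' Per-microplot cumulative emissions and hot-moment attribution
#'
#' Convenience wrapper running [interpolate_fluxes()],
#' [cumulative_emission()] and [hot_moment_share()] for every microplot in
#' a QC'd flux table (rows with `qc_status != "ok"` are dropped first).
#'
#' @param fluxes Flux records from [process_closures()] (needs `patch`,
#'   `microplot`, `date`, `n2o_flux`, `qc_status`).
#' @param calendar Event calendar.
#' @param period_start,period_end Crop period boundaries.
#' @param ... Passed to [identify_hot_moments()].
#' @return Data frame, one row per microplot: `patch`, `microplot`,
#'   `cumulative`, `hot_emission`, `background_emission`, `share_pct`,
#'   `n_campaigns`.
#' @export
summarise_emissions <- function(fluxes, calendar, period_start, period_end,
                                ...) {
  ok <- fluxes[fluxes$qc_status == "ok" & is.finite(fluxes$n2o_flux), ]
  if (nrow(ok) == 0) stop("no valid fluxes")
  mask <- identify_hot_moments(calendar, period_start, period_end, ...)
  key <- interaction(ok$patch, ok$microplot, drop = TRUE)
  rows <- lapply(split(ok, key), function(d) {
    ser <- interpolate_fluxes(d$date, d$n2o_flux, period_start, period_end)
    hs <- hot_moment_share(ser, mask)
    data.frame(patch = d$patch[1], microplot = d$microplot[1],
               cumulative = hs$total_emission,
               hot_emission = hs$hot_emission,
               background_emission = hs$background_emission,
               share_pct = hs$share_pct,
               n_campaigns = length(unique(d$date)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$patch, res$microplot), ]
}
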