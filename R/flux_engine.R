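## flux_engine: one chamber closure -> QC'd N2O and CO2 fluxes.
##
## The chamber method assumes linear concentration accumulation in the
## headspace during the 60-min closure; the flux follows from the fitted
## slope via the ideal gas law. Closures whose CO2 trace does not increase
## (opaque chamber, so ecosystem respiration must raise CO2) are discarded
## entirely; gross single-point outliers are screened with a 6 x IQR band
## on regression residuals.

## internal OLS on (times, conc); returns slope/intercept/residuals/r2.
.ols <- function(times, conc) {
  tbar <- mean(times)
  cbar <- mean(conc)
  sxx <- sum((times - tbar)^2)
  slope <- sum((times - tbar) * (conc - cbar)) / sxx
  intercept <- cbar - slope * tbar
  fitted <- intercept + slope * times
  res <- conc - fitted
  sst <- sum((conc - cbar)^2)
  sse <- sum(res^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  list(slope = slope, intercept = intercept, residuals = res,
       r2 = r2, sse = sse, n = length(times))
}

#' Fit the in-chamber concentration slope
#'
#' Ordinary least-squares fit of gas concentration against elapsed closure
#' time, the basis of the linear chamber flux model. Residuals are returned
#' for downstream outlier screening.
#'
#' @param times Sample times in minutes since chamber closure (typically
#'   0, 20, 40, 60). At least 3 finite points are required.
#' @param conc Gas concentrations in ppm, same length as `times`.
#' @return A list with elements `slope` (ppm min^-1), `intercept` (ppm),
#'   `residuals` (ppm), `r2`, and `n`. `r2` is `NA` for a perfectly
#'   constant series (zero total variance).
#' @examples
#' fit_concentration_slope(c(0, 20, 40, 60), c(300, 320, 340, 360))$slope
#' @export
fit_concentration_slope <- function(times, conc) {
  ok <- is.finite(times) & is.finite(conc)
  if (sum(ok) < 3) {
    stop(errorCondition("fewer than 3 finite concentration points",
                        class = c("patchflux_too_few_points", "error")))
  }
  times <- times[ok]
  conc <- conc[ok]
  if (any(diff(order(times)) < 0) || anyDuplicated(times)) {
    o <- order(times)
    times <- times[o]
    conc <- conc[o]
    if (anyDuplicated(times)) stop("sample times must be distinct")
  }
  .ols(times, conc)[c("slope", "intercept", "residuals", "r2", "n")]
}

## residual acceptance band [Q1 - k*IQR - tol, Q3 + k*IQR + tol].
## tol guards the degenerate all-equal-residual case (IQR = 0), where
## floating-point dust on an exactly linear series must not be flagged.
.iqr_band <- function(residuals, k = 6, tol = 1e-9) {
  q <- quantile(residuals, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(q[1] - k * iqr - tol, q[2] + k * iqr + tol)
}

#' Screen concentration points against an IQR residual band
#'
#' Flags points whose OLS residual falls outside
#' `[Q1 - k*IQR, Q3 + k*IQR]` of a residual distribution and removes them
#' by greedy best-subset deletion: among band violators the point whose
#' removal most reduces the refit residual sum of squares is dropped first,
#' the line is refit, and screening repeats until no violations remain or
#' `max_remove` points have been dropped. Refit-based selection matters for
#' short series, where a gross spike at a high-leverage end point does not
#' carry the largest raw residual.
#'
#' With four samples per closure the band of a closure's own residuals can
#' never flag a single spike (the spike inflates the IQR in proportion to
#' itself), so callers processing whole campaigns should pass a `band`
#' pooled across closures; see [process_closures()].
#'
#' @param times,conc Closure sample times (min) and concentrations (ppm).
#' @param k IQR multiplier (default 6).
#' @param band Optional numeric length-2 acceptance interval for residuals.
#'   Defaults to the band of this series' own residuals.
#' @param max_remove Maximum number of points to drop (default `n - 3`, so
#'   a valid 3-point fit always remains).
#' @return Logical vector, `TRUE` for retained points.
#' @export
remove_outliers_iqr <- function(times, conc, k = 6, band = NULL,
                                max_remove = length(times) - 3L) {
  n <- length(times)
  stopifnot(length(conc) == n, n >= 3)
  keep <- rep(TRUE, n)
  own_band <- is.null(band)
  max_remove <- max(0L, as.integer(max_remove))
  repeat {
    fit <- .ols(times[keep], conc[keep])
    res <- rep(NA_real_, n)
    res[keep] <- fit$residuals
    b <- if (own_band) .iqr_band(fit$residuals, k) else band
    viol <- keep & (res < b[1] | res > b[2])
    if (!any(viol) || sum(!keep) >= max_remove) break
    ## candidate whose deletion minimises the refit SSE
    cand <- which(viol)
    sse <- vapply(cand, function(i) {
      kk <- keep
      kk[i] <- FALSE
      .ols(times[kk], conc[kk])$sse
    }, numeric(1))
    keep[cand[which.min(sse)]] <- FALSE
  }
  keep
}

#' CO2 plausibility check for an opaque chamber closure
#'
#' In a dark chamber, ecosystem respiration must raise the headspace CO2
#' concentration. A non-increasing CO2 slope therefore signals a leak or
#' sampling fault, and the closure's N2O flux is rejected along with the
#' CO2 flux. A perfectly flat trace (slope exactly 0) fails.
#'
#' @param times Sample times (min).
#' @param co2 CO2 concentrations (ppm).
#' @return `TRUE` if the OLS CO2 slope is strictly positive.
#' @export
qc_co2_check <- function(times, co2) {
  fit_concentration_slope(times, co2)$slope > 0
}

#' Chamber flux from a concentration slope (ideal gas law)
#'
#' `F = p V / (R T A) * dc/dt`, with the slope supplied in ppm min^-1 and
#' converted internally to mole fraction per second. Negative fluxes
#' (uptake) are retained; the sign of the flux equals the sign of the
#' slope. R = 8.314 m3 Pa K^-1 mol^-1.
#'
#' @param slope Concentration slope, ppm min^-1 (vectorised).
#' @param pressure Ambient air pressure, Pa.
#' @param volume Chamber volume, m3.
#' @param temperature Air temperature, K (> 0).
#' @param area Chamber basal area, m2 (> 0).
#' @return Flux in umol m^-2 s^-1.
#' @examples
#' compute_flux(1, pressure = 101325, volume = 0.076,
#'              temperature = 293.15, area = 0.193)
#' @export
compute_flux <- function(slope, pressure, volume, temperature, area) {
  if (any(!is.finite(pressure)) || any(!is.finite(volume)) ||
      any(!is.finite(temperature)) || any(!is.finite(area))) {
    stop("chamber parameters must be finite")
  }
  if (any(temperature <= 0)) stop("temperature must be positive (K)")
  if (any(area <= 0)) stop("chamber area must be positive")
  if (any(volume <= 0) || any(pressure <= 0)) {
    stop("pressure and volume must be positive")
  }
  ## ppm min^-1 -> mol fraction s^-1 is 1e-6 / 60; result mol -> umol is 1e6
  (pressure * volume) / (.R_GAS * temperature * area) * slope / 60
}

#' Convert a molar flux to mass-based reporting units
#'
#' N2O fluxes are reported on the nitrogen basis (28 g N per mol N2O, two N
#' atoms) in ug N2O-N m^-2 h^-1; CO2 fluxes on the carbon basis (12 g C per
#' mol) in mg CO2-C m^-2 h^-1.
#'
#' @param flux Flux in umol gas m^-2 s^-1 (vectorised).
#' @param gas `"N2O"` or `"CO2"`.
#' @return Converted flux (ug N2O-N m^-2 h^-1 or mg CO2-C m^-2 h^-1).
#' @export
convert_flux_units <- function(flux, gas = c("N2O", "CO2")) {
  gas <- match.arg(gas)
  switch(gas,
    N2O = flux * 28 * 3600,        # umol -> ug N, per hour
    CO2 = flux * 12 * 3600 / 1000  # umol -> ug C -> mg C, per hour
  )
}

#' Process a table of chamber closures into QC'd flux records
#'
#' Runs the full per-closure chain: OLS slope fit for each gas, outlier
#' screening against a 6 x IQR residual band pooled across all closures in
#' the batch (per gas), refit, the CO2 plausibility check, and the
#' ideal-gas flux calculation with unit conversion.
#'
#' @param closures Long-format data frame with one row per gas sample and
#'   columns `closure_id`, `t_min`, `n2o_ppm`, `co2_ppm`, `pressure_pa`,
#'   `air_temp_k`, `volume_m3`, `area_m2`, plus any identifying columns
#'   (`patch`, `microplot`, `date`), which are carried through.
#' @param iqr_k IQR multiplier for outlier screening (default 6).
#' @param pool_residuals If `TRUE` (default) the residual band is estimated
#'   from first-pass residuals pooled over all closures of the batch, per
#'   gas; if `FALSE` each closure uses its own residual band (toothless for
#'   4-point closures; see [remove_outliers_iqr()]).
#' @return Data frame with one row per closure: identifiers, per-gas
#'   slopes (ppm min^-1), r2, points removed, `n2o_flux`
#'   (ug N2O-N m^-2 h^-1), `co2_flux` (mg CO2-C m^-2 h^-1), and
#'   `qc_status` (`"ok"`, `"co2_decrease"` or `"too_few_points"`).
#'   Fluxes of non-`"ok"` closures are `NA`.
#' @export
process_closures <- function(closures, iqr_k = 6, pool_residuals = TRUE) {
  need <- c("closure_id", "t_min", "n2o_ppm", "co2_ppm",
            "pressure_pa", "air_temp_k", "volume_m3", "area_m2")
  miss <- setdiff(need, names(closures))
  if (length(miss)) stop("closures lacks columns: ", paste(miss, collapse = ", "))

  idx <- split(seq_len(nrow(closures)), closures$closure_id)

  ## first pass: per-closure OLS residuals for the pooled band
  first <- lapply(idx, function(i) {
    ti <- closures$t_min[i]
    lapply(list(n2o = closures$n2o_ppm[i], co2 = closures$co2_ppm[i]),
           function(cc) {
             ok <- is.finite(ti) & is.finite(cc)
             if (sum(ok) < 3) return(NULL)
             .ols(ti[ok], cc[ok])$residuals
           })
  })
  band <- lapply(c(n2o = "n2o", co2 = "co2"), function(g) {
    if (!pool_residuals) return(NULL)
    pooled <- unlist(lapply(first, `[[`, g), use.names = FALSE)
    if (is.null(pooled) || length(pooled) < 4) return(NULL)
    .iqr_band(pooled, iqr_k)
  })

  id_cols <- intersect(c("patch", "microplot", "date", "crop"), names(closures))
  rows <- lapply(names(idx), function(cid) {
    i <- idx[[cid]]
    ti <- closures$t_min[i]
    out <- data.frame(closure_id = cid, stringsAsFactors = FALSE)
    for (cc in id_cols) out[[cc]] <- closures[[cc]][i[1]]
    p <- closures$pressure_pa[i[1]]
    tk <- closures$air_temp_k[i[1]]
    v <- closures$volume_m3[i[1]]
    a <- closures$area_m2[i[1]]

    gas_fit <- function(conc, b) {
      ok <- is.finite(ti) & is.finite(conc)
      if (sum(ok) < 3) return(NULL)
      keep <- ok
      keep[ok] <- remove_outliers_iqr(ti[ok], conc[ok], k = iqr_k, band = b,
                                      max_remove = sum(ok) - 3L)
      fit <- .ols(ti[keep], conc[keep])
      fit$removed <- sum(ok) - sum(keep)
      fit
    }
    fn <- gas_fit(closures$n2o_ppm[i], band$n2o)
    fc <- gas_fit(closures$co2_ppm[i], band$co2)

    if (is.null(fn) || is.null(fc)) {
      status <- "too_few_points"
    } else if (fc$slope <= 0) {
      status <- "co2_decrease"
    } else {
      status <- "ok"
    }
    out$n2o_slope <- if (is.null(fn)) NA_real_ else fn$slope
    out$co2_slope <- if (is.null(fc)) NA_real_ else fc$slope
    out$n2o_r2 <- if (is.null(fn)) NA_real_ else fn$r2
    out$co2_r2 <- if (is.null(fc)) NA_real_ else fc$r2
    out$points_removed_n2o <- if (is.null(fn)) NA_integer_ else fn$removed
    out$points_removed_co2 <- if (is.null(fc)) NA_integer_ else fc$removed
    if (status == "ok") {
      out$n2o_flux <- convert_flux_units(
        compute_flux(fn$slope, p, v, tk, a), "N2O")
      out$co2_flux <- convert_flux_units(
        compute_flux(fc$slope, p, v, tk, a), "CO2")
    } else {
      out$n2o_flux <- NA_real_
      out$co2_flux <- NA_real_
    }
    out$qc_status <- status
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if ("date" %in% names(res)) res$date <- as.Date(res$date)
  res
}
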