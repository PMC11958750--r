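## synth_campaign: synthetic field campaigns with known ground truth.
##
## Emulates a patch-scale chamber monitoring design: patches of six
## microplots along a ~30 m transect, a latent daily N2O flux field with
## event-driven pulses, four-point chamber closures whose concentration
## slopes encode the true flux through the ideal gas law, and labelled
## corrupted closures (decreasing CO2; one gross N2O outlier point) for QC
## sensitivity testing. Every stochastic draw is governed by `seed`.

#' Configuration for a synthetic campaign
#'
#' Defaults describe one 180-day crop period on six patches of six
#' microplots, a baseline flux of 10 ug N2O-N m^-2 h^-1, event pulses of
#' 2.5 x baseline decaying over ~6 days (two mineral fertilizations and two
#' heavy rains), sand contents spanning 68-94 %, and GC-grade concentration
#' noise of 0.005 ppm on N2O. These settings place the true hot-moment
#' share near 37 % of the cumulative emission.
#'
#' @param n_patches Number of patches.
#' @param microplots_per_patch Microplots per patch (default 6).
#' @param period_start,period_end Crop period boundaries (`Date`).
#' @param baseline_flux Latent baseline N2O flux, ug N2O-N m^-2 h^-1.
#' @param pulse_amplitude Event pulse peak as a multiple of baseline (>= 0).
#' @param pulse_decay_days Exponential decay time of pulses, days (> 0).
#' @param sand_range Length-2 range of sand contents, %.
#' @param noise_sd_conc Gaussian noise sd on N2O concentrations, ppm
#'   (CO2 samples receive 1000 x this, matching its ~1000-fold ambient
#'   level).
#' @param corrupt_closure_rate Fraction of closures corrupted (in [0, 1]).
#' @param n_fert_events,n_rain_events Event counts for the calendar.
#' @param fert_n_rate N applied per fertilization event, kg N ha^-1.
#' @param sand_sensitivity Strength of the sand-driven flux multiplier.
#' @param chamber_volume,chamber_area Chamber constants, m3 / m2.
#' @param pressure,air_temperature Ambient conditions, Pa / K.
#' @param seed Integer seed controlling all draws.
#' @return A validated list of class `"truth_config"`.
#' @export
truth_config <- function(n_patches = 6, microplots_per_patch = 6,
                         period_start = as.Date("2023-03-01"),
                         period_end = as.Date("2023-08-28"),
                         baseline_flux = 10, pulse_amplitude = 2.5,
                         pulse_decay_days = 6, sand_range = c(68, 94),
                         noise_sd_conc = 0.005, corrupt_closure_rate = 0,
                         n_fert_events = 2, n_rain_events = 2,
                         fert_n_rate = 80, sand_sensitivity = 0.5,
                         chamber_volume = 0.076, chamber_area = 0.193,
                         pressure = 101325, air_temperature = 293.15,
                         seed = 1) {
  cfg <- list(n_patches = as.integer(n_patches),
              microplots_per_patch = as.integer(microplots_per_patch),
              period_start = as.Date(period_start),
              period_end = as.Date(period_end),
              baseline_flux = baseline_flux,
              pulse_amplitude = pulse_amplitude,
              pulse_decay_days = pulse_decay_days,
              sand_range = as.numeric(sand_range),
              noise_sd_conc = noise_sd_conc,
              corrupt_closure_rate = corrupt_closure_rate,
              n_fert_events = as.integer(n_fert_events),
              n_rain_events = as.integer(n_rain_events),
              fert_n_rate = fert_n_rate,
              sand_sensitivity = sand_sensitivity,
              chamber_volume = chamber_volume, chamber_area = chamber_area,
              pressure = pressure, air_temperature = air_temperature,
              seed = as.integer(seed))
  class(cfg) <- "truth_config"
  validate_truth_config(cfg)
}

#' @rdname truth_config
#' @param cfg A `truth_config` object.
#' @export
validate_truth_config <- function(cfg) {
  bad <- function(msg) {
    stop(errorCondition(paste("invalid configuration:", msg),
                        class = c("patchflux_config_error", "error")))
  }
  if (cfg$n_patches < 1 || cfg$microplots_per_patch < 1) {
    bad("patch/microplot counts must be >= 1")
  }
  if (!(cfg$period_end > cfg$period_start)) {
    bad("period_end must follow period_start")
  }
  if (cfg$baseline_flux < 0) bad("baseline_flux must be >= 0")
  if (cfg$pulse_amplitude < 0) bad("pulse_amplitude must be >= 0")
  if (cfg$pulse_decay_days <= 0) bad("pulse_decay_days must be > 0")
  if (length(cfg$sand_range) != 2 || diff(cfg$sand_range) < 0 ||
      cfg$sand_range[1] < 0 || cfg$sand_range[2] > 100) {
    bad("sand_range must be an increasing pair within [0, 100]")
  }
  if (cfg$noise_sd_conc < 0) bad("noise_sd_conc must be >= 0")
  if (cfg$corrupt_closure_rate < 0 || cfg$corrupt_closure_rate > 1) {
    bad("corrupt_closure_rate must be in [0, 1]")
  }
  if (cfg$n_fert_events < 0 || cfg$n_rain_events < 0) {
    bad("event counts must be >= 0")
  }
  if (cfg$chamber_volume <= 0 || cfg$chamber_area <= 0 ||
      cfg$pressure <= 0 || cfg$air_temperature <= 0) {
    bad("chamber constants and ambient conditions must be positive")
  }
  invisible(cfg)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate static soil/terrain profiles per microplot
#'
#' Draws patch-level mean sand contents spanning `cfg$sand_range` with
#' microplot jitter that grows with patch sandiness (sandier patches are
#' texturally more variable), splits the non-sand remainder into silt and
#' clay, and adds total carbon/nitrogen, pH, bulk density (within
#' 1.5-1.9 g cm^-3) and transect elevations. Patches in the less-sandy
#' half are classed `"high"` yield potential, the rest `"low"`.
#'
#' @param cfg A [truth_config()].
#' @return Data frame, one row per microplot: `patch`, `microplot`,
#'   `position_m`, `sand`, `silt`, `clay` (summing to 100), `tc`, `tn`,
#'   `ph`, `bd`, `elevation`, `yield_class`.
#' @export
generate_soil_profiles <- function(cfg) {
  validate_truth_config(cfg)
  .with_seed(cfg$seed + 1L, {
    lo <- cfg$sand_range[1]
    hi <- cfg$sand_range[2]
    m <- cfg$microplots_per_patch
    span <- hi - lo
    ## patch means spaced over the inner range, shuffled over patch ids
    centers <- if (cfg$n_patches == 1) (lo + hi) / 2 else {
      seq(lo + 0.15 * span, hi - 0.15 * span, length.out = cfg$n_patches)
    }
    if (length(centers) > 1) centers <- sample(centers)
    rows <- lapply(seq_len(cfg$n_patches), function(p) {
      jitter_sd <- if (span == 0) 0 else {
        max(0, 1 + 3 * (centers[p] - lo - 0.15 * span) /
              max(span * 0.7, 1e-9)) * span / 26
      }
      sand <- pmin(hi, pmax(lo, centers[p] + rnorm(m, 0, jitter_sd)))
      silt_frac <- runif(m, 0.65, 0.75)
      silt <- (100 - sand) * silt_frac
      clay <- 100 - sand - silt
      pos <- if (m == 1) 0 else seq(0, 30, length.out = m)
      base_elev <- runif(1, 50, 60)
      grade <- runif(1, 0.005, 0.04)          # 0.5-4 % transect slope
      tc <- runif(m, 0.6, 1.0)
      data.frame(patch = p, microplot = seq_len(m), position_m = pos,
                 sand = sand, silt = silt, clay = clay,
                 tc = tc, tn = tc / runif(m, 9, 12),
                 ph = runif(m, 5.4, 6.4), bd = runif(m, 1.65, 1.80),
                 elevation = base_elev + grade * pos +
                   rnorm(m, 0, 0.02))
    })
    prof <- do.call(rbind, rows)
    patch_sand <- tapply(prof$sand, prof$patch, mean)
    high <- names(sort(patch_sand))[seq_len(floor(cfg$n_patches / 2))]
    prof$yield_class <- ifelse(prof$patch %in% as.integer(high) |
                                 cfg$n_patches == 1, "high", "low")
    rownames(prof) <- NULL
    prof
  })
}

#' Generate a dated event calendar
#'
#' Places `n_fert_events` mineral fertilizations (each `fert_n_rate`
#' kg N ha^-1) and `n_rain_events` heavy rains (22-45 mm d^-1, i.e. above
#' the 20 mm d^-1 trigger) at sorted random dates in the interior of the
#' crop period, leaving room for the post-event windows.
#'
#' @param cfg A [truth_config()].
#' @return Event calendar data frame (`date`, `kind`, `magnitude`),
#'   sorted by date; zero-row when both event counts are 0.
#' @export
generate_event_calendar <- function(cfg) {
  validate_truth_config(cfg)
  .with_seed(cfg$seed + 2L, {
    len <- as.numeric(cfg$period_end - cfg$period_start)
    pick <- function(n, tail_gap) {
      hi <- max(len - tail_gap, 15)
      sort(sample(seq(14, hi), n))
    }
    cal <- data.frame(date = as.Date(character()), kind = character(),
                      magnitude = numeric())
    if (cfg$n_fert_events > 0) {
      cal <- rbind(cal, data.frame(
        date = cfg$period_start + pick(cfg$n_fert_events, 30),
        kind = "mineral_fert", magnitude = cfg$fert_n_rate))
    }
    if (cfg$n_rain_events > 0) {
      cal <- rbind(cal, data.frame(
        date = cfg$period_start + pick(cfg$n_rain_events, 14),
        kind = "rain", magnitude = runif(cfg$n_rain_events, 22, 45)))
    }
    cal <- cal[order(cal$date), ]
    rownames(cal) <- NULL
    validate_event_calendar(cal)
    cal
  })
}

#' Generate daily weather consistent with the event calendar
#'
#' Seasonal air temperature (annual sinusoid around 9.9 degC) and daily
#' precipitation with ordinary wet days capped below the heavy-rain
#' trigger; calendar rain-event days carry their event magnitude.
#'
#' @param cfg A [truth_config()].
#' @param calendar Event calendar from [generate_event_calendar()].
#' @return Data frame: `date`, `air_temp_c`, `precip_mm`.
#' @export
generate_weather <- function(cfg, calendar) {
  validate_truth_config(cfg)
  .with_seed(cfg$seed + 5L, {
    grid <- seq(cfg$period_start, cfg$period_end, by = "day")
    doy <- as.integer(format(grid, "%j"))
    temp <- 9.9 + 8 * sin(2 * pi * (doy - 105) / 365) +
      rnorm(length(grid), 0, 1.5)
    precip <- ifelse(runif(length(grid)) < 0.3,
                     pmin(stats::rexp(length(grid), 1 / 4), 18), 0)
    rain <- calendar[calendar$kind == "rain", ]
    precip[match(as.Date(rain$date), grid)] <- rain$magnitude
    data.frame(date = grid, air_temp_c = temp, precip_mm = precip)
  })
}

#' Generate daily microclimate logger series per microplot
#'
#' Volumetric soil moisture follows texture (sandier microplots hold less
#' water) plus a decaying response to precipitation; soil temperature is a
#' damped, lagged version of air temperature.
#'
#' @param cfg A [truth_config()].
#' @param profiles Soil profiles from [generate_soil_profiles()].
#' @param weather Daily weather from [generate_weather()].
#' @return Data frame: `patch`, `microplot`, `date`, `theta_v`
#'   (volumetric fraction), `soil_temp_c`, `air_temp_c`.
#' @export
generate_loggers <- function(cfg, profiles, weather) {
  validate_truth_config(cfg)
  .with_seed(cfg$seed + 6L, {
    nday <- nrow(weather)
    wet <- stats::filter(weather$precip_mm, 0.85, "recursive")
    soil_t <- stats::filter(weather$air_temp_c, 0.7, "recursive") * 0.3
    rows <- lapply(seq_len(nrow(profiles)), function(i) {
      base <- 0.32 - 0.002 * profiles$sand[i]
      theta <- base + 0.004 * as.numeric(wet) +
        rnorm(nday, 0, 0.005)
      porosity <- 1 - profiles$bd[i] / .PARTICLE_DENSITY
      theta <- pmin(pmax(theta, 0.03), 0.95 * porosity)
      data.frame(patch = profiles$patch[i],
                 microplot = profiles$microplot[i],
                 date = weather$date, theta_v = theta,
                 soil_temp_c = as.numeric(soil_t) + rnorm(nday, 0, 0.3),
                 air_temp_c = weather$air_temp_c + rnorm(nday, 0, 0.2))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate the latent daily flux field and its ground truth
#'
#' Daily true flux per microplot:
#' `baseline * modifier + sum of event pulses`, with
#' `modifier = exp(sand_sensitivity * (sand - midrange)/10)` (the only
#' spatial structure, keeping the sand-CV relation testable) and each
#' pulse `amplitude * baseline * exp(-dt/decay)` for `dt >= 0` days since
#' the event. The true cumulative emission and hot-moment share are
#' computed from the daily series with the same trapezoidal rule and
#' window definition used downstream.
#'
#' @param cfg A [truth_config()].
#' @param profiles Soil profiles from [generate_soil_profiles()].
#' @param calendar Event calendar from [generate_event_calendar()].
#' @return List with `daily` (long data frame `patch`, `microplot`,
#'   `date`, `true_flux`, `true_co2_flux`), `summary` (per microplot:
#'   `true_cumulative` g N2O-N ha^-1, `true_share_pct`), and `mask` (the
#'   hot-moment day mask used).
#' @export
generate_true_flux_field <- function(cfg, profiles, calendar) {
  validate_truth_config(cfg)
  if (nrow(calendar) > 0) {
    ev <- as.Date(calendar$date)
    if (any(ev < cfg$period_start | ev > cfg$period_end)) {
      stop("calendar events outside the crop period")
    }
  }
  grid <- seq(cfg$period_start, cfg$period_end, by = "day")
  pulse <- rep(0, length(grid))
  if (nrow(calendar) > 0) {
    for (j in seq_len(nrow(calendar))) {
      dt <- as.numeric(grid - as.Date(calendar$date[j]))
      on <- dt >= 0
      pulse[on] <- pulse[on] + cfg$pulse_amplitude * cfg$baseline_flux *
        exp(-dt[on] / cfg$pulse_decay_days)
    }
  }
  mask <- identify_hot_moments(calendar, cfg$period_start, cfg$period_end)
  mid <- mean(cfg$sand_range)
  daily <- lapply(seq_len(nrow(profiles)), function(i) {
    mod <- exp(cfg$sand_sensitivity * (profiles$sand[i] - mid) / 10)
    flux <- cfg$baseline_flux * mod + pulse
    data.frame(patch = profiles$patch[i],
               microplot = profiles$microplot[i],
               date = grid, true_flux = flux,
               true_co2_flux = 40 + 2.5 * flux)
  })
  summary <- do.call(rbind, lapply(daily, function(d) {
    ser <- data.frame(date = d$date, flux = d$true_flux)
    hs <- hot_moment_share(ser, mask)
    data.frame(patch = d$patch[1], microplot = d$microplot[1],
               true_cumulative = hs$total_emission,
               true_share_pct = hs$share_pct)
  }))
  daily <- do.call(rbind, daily)
  rownames(daily) <- rownames(summary) <- NULL
  list(daily = daily, summary = summary, mask = mask)
}

#' Campaign schedule: biweekly grid plus post-event intensification
#'
#' Regular campaigns every `every` days from the period start, plus
#' `post_event_offsets` days after each calendar event (the field protocol
#' of returning within a week of fertilization or heavy rain).
#'
#' @param cfg A [truth_config()].
#' @param calendar Event calendar.
#' @param every Regular campaign interval, days (default 14).
#' @param post_event_offsets Extra campaign offsets after each event,
#'   days (default `c(1, 3, 7)`).
#' @return Sorted vector of unique campaign `Date`s within the period.
#' @export
campaign_schedule <- function(cfg, calendar, every = 14,
                              post_event_offsets = c(1, 3, 7)) {
  validate_truth_config(cfg)
  len <- as.numeric(cfg$period_end - cfg$period_start)
  days <- seq(0, len, by = every)
  if (nrow(calendar) > 0) {
    ev <- as.numeric(as.Date(calendar$date) - cfg$period_start)
    days <- c(days, outer(ev, post_event_offsets, `+`))
  }
  sort(unique(cfg$period_start + days[days >= 0 & days <= len]))
}

#' Sample chamber closures from the true flux field
#'
#' For every microplot and scheduled date, builds a four-point (0, 20, 40,
#' 60 min) concentration series whose OLS slope encodes the true flux
#' inverted through the ideal gas law, adds Gaussian concentration noise,
#' and corrupts a labelled fraction of closures either by reversing the
#' CO2 trend or by one gross N2O outlier point (+0.5 ppm or 100 x the
#' noise sd, whichever is larger).
#'
#' @param truth Output of [generate_true_flux_field()].
#' @param schedule Campaign dates (see [campaign_schedule()]); must be
#'   non-empty and within the period.
#' @param cfg A [truth_config()].
#' @param corrupt_modes Corruption modes to draw from (default both);
#'   restrict to a single mode for targeted QC sensitivity tests.
#' @return Long data frame, four rows per closure: `closure_id`, `patch`,
#'   `microplot`, `date`, `t_min`, `n2o_ppm`, `co2_ppm`, `pressure_pa`,
#'   `air_temp_k`, `volume_m3`, `area_m2`, and corruption labels
#'   `corrupt_mode` (`"none"`, `"co2_decrease"`, `"n2o_outlier"`) and
#'   `outlier_t_min` (`NA` unless an outlier was injected).
#' @export
sample_campaign <- function(truth, schedule, cfg,
                            corrupt_modes = c("co2_decrease",
                                              "n2o_outlier")) {
  corrupt_modes <- match.arg(corrupt_modes, several.ok = TRUE)
  validate_truth_config(cfg)
  schedule <- as.Date(schedule)
  if (length(schedule) == 0) stop("empty campaign schedule")
  daily <- truth$daily
  if (any(schedule < min(daily$date) | schedule > max(daily$date))) {
    stop("schedule dates outside the simulated period")
  }
  .with_seed(cfg$seed + 4L, {
    sub <- daily[daily$date %in% schedule, ]
    n_clo <- nrow(sub)
    t_min <- c(0, 20, 40, 60)
    ## slope (ppm min^-1) from flux via the ideal-gas relation
    inv <- (.R_GAS * cfg$air_temperature * cfg$chamber_area) /
      (cfg$pressure * cfg$chamber_volume) * 60
    n2o_slope <- sub$true_flux / (28 * 3600) * inv
    co2_slope <- sub$true_co2_flux * 1000 / (12 * 3600) * inv
    corrupt <- runif(n_clo) < cfg$corrupt_closure_rate
    mode <- ifelse(corrupt,
                   sample(corrupt_modes, n_clo, replace = TRUE), "none")
    spike <- max(0.5, 100 * cfg$noise_sd_conc)
    out_pt <- ifelse(mode == "n2o_outlier", sample(4L, n_clo, TRUE),
                     NA_integer_)
    rows <- vector("list", n_clo)
    for (i in seq_len(n_clo)) {
      n2o <- 0.332 + n2o_slope[i] * t_min +
        rnorm(4, 0, cfg$noise_sd_conc)
      s_co2 <- if (mode[i] == "co2_decrease") {
        -abs(co2_slope[i]) - 0.2
      } else {
        co2_slope[i]
      }
      co2 <- 420 + s_co2 * t_min + rnorm(4, 0, 1000 * cfg$noise_sd_conc)
      if (mode[i] == "n2o_outlier") {
        n2o[out_pt[i]] <- n2o[out_pt[i]] + spike
      }
      rows[[i]] <- data.frame(
        closure_id = sprintf("p%02d_m%02d_%s", sub$patch[i],
                             sub$microplot[i], format(sub$date[i])),
        patch = sub$patch[i], microplot = sub$microplot[i],
        date = sub$date[i], t_min = t_min, n2o_ppm = n2o, co2_ppm = co2,
        pressure_pa = cfg$pressure, air_temp_k = cfg$air_temperature,
        volume_m3 = cfg$chamber_volume, area_m2 = cfg$chamber_area,
        corrupt_mode = mode[i],
        outlier_t_min = if (is.na(out_pt[i])) NA_real_ else
          t_min[out_pt[i]])
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a complete synthetic campaign to CSV files
#'
#' Convenience driver generating profiles, calendar, weather, loggers,
#' truth field, schedule and closures from one configuration and writing
#' `closures.csv`, `truth.csv`, `truth_summary.csv`, `profiles.csv`,
#' `events.csv`, `weather.csv` and `loggers.csv` (ISO-8601 dates, UTF-8).
#'
#' @param cfg A [truth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_campaign <- function(cfg, dir) {
  validate_truth_config(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  profiles <- generate_soil_profiles(cfg)
  calendar <- generate_event_calendar(cfg)
  weather <- generate_weather(cfg, calendar)
  loggers <- generate_loggers(cfg, profiles, weather)
  truth <- generate_true_flux_field(cfg, profiles, calendar)
  schedule <- campaign_schedule(cfg, calendar)
  closures <- sample_campaign(truth, schedule, cfg)
  w <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  w(closures, "closures.csv")
  w(truth$daily, "truth.csv")
  w(truth$summary, "truth_summary.csv")
  w(profiles, "profiles.csv")
  w(calendar, "events.csv")
  w(weather, "weather.csv")
  w(loggers, "loggers.csv")
  invisible(list(profiles = profiles, calendar = calendar,
                 weather = weather, loggers = loggers, truth = truth,
                 schedule = schedule, closures = closures))
}
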