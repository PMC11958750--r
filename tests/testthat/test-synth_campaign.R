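test_that("soil profiles respect texture closure, ranges and determinism", {
  cfg <- truth_config(n_patches = 4, microplots_per_patch = 6,
                      sand_range = c(68, 94), seed = 3)
  p1 <- generate_soil_profiles(cfg)
  p2 <- generate_soil_profiles(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 24)
  expect_true(all(p1$sand >= 68 & p1$sand <= 94))
  expect_equal(p1$sand + p1$silt + p1$clay, rep(100, 24), tolerance = 0.01)
  expect_true(all(p1$bd >= 1.5 & p1$bd <= 1.9))
  expect_setequal(unique(p1$yield_class), c("high", "low"))
  # high-yield patches are the less sandy ones
  ps <- tapply(p1$sand, p1$patch, mean)
  yc <- tapply(p1$yield_class, p1$patch, unique)
  expect_true(max(ps[yc == "high"]) < min(ps[yc == "low"]))

  # degenerate range pins sand exactly
  d <- generate_soil_profiles(clean_cfg())
  expect_equal(d$sand, rep(80, 2))
  expect_equal(d$silt + d$clay, rep(20, 2))

  expect_error(truth_config(sand_range = c(94, 68)),
               class = "patchflux_config_error")
  expect_error(truth_config(corrupt_closure_rate = 1.5),
               class = "patchflux_config_error")
  expect_error(truth_config(pulse_decay_days = 0),
               class = "patchflux_config_error")
})

test_that("event calendars have the requested events, in-period dates and valid magnitudes", {
  cfg <- truth_config(n_fert_events = 2, n_rain_events = 1, seed = 9)
  cal <- generate_event_calendar(cfg)
  expect_identical(cal, generate_event_calendar(cfg))
  expect_equal(nrow(cal), 3)
  expect_equal(sum(cal$kind == "mineral_fert"), 2)
  expect_equal(sum(cal$kind == "rain"), 1)
  expect_true(all(cal$date >= cfg$period_start & cal$date <= cfg$period_end))
  expect_true(all(cal$magnitude[cal$kind == "rain"] > 20))
  expect_true(all(cal$magnitude[cal$kind != "rain"] > 0))

  empty <- generate_event_calendar(truth_config(n_fert_events = 0,
                                                n_rain_events = 0))
  expect_equal(nrow(empty), 0)

  w <- generate_weather(cfg, cal)
  expect_equal(nrow(w), as.numeric(cfg$period_end - cfg$period_start) + 1)
  rain_day <- w$precip_mm[match(cal$date[cal$kind == "rain"], w$date)]
  expect_true(all(rain_day > 20))
  expect_true(all(w$precip_mm[!w$date %in% cal$date] <= 20))
})

test_that("flux field obeys the analytic forms: constant, zero and one-pulse cases", {
  # no pulses: constant series, share equals the window-day fraction
  cfg <- clean_cfg(pulse_amplitude = 0)
  prof <- generate_soil_profiles(cfg)
  cal <- generate_event_calendar(cfg)
  truth <- generate_true_flux_field(cfg, prof, cal)
  one <- truth$daily[truth$daily$microplot == 1, ]
  expect_equal(one$true_flux, rep(10, nrow(one)))
  m <- as.numeric(truth$mask$hot)
  wfrac <- sum((m[-1] + m[-length(m)]) / 2) / (length(m) - 1)
  expect_equal(truth$summary$true_share_pct,
               rep(100 * wfrac, 2), tolerance = 1e-9)

  # zero baseline: all-zero field
  z <- generate_true_flux_field(clean_cfg(baseline_flux = 0), prof, cal)
  expect_equal(unique(z$daily$true_flux), 0)
  expect_equal(z$summary$true_cumulative, rep(0, 2))

  # single pulse: closed form == quadrature oracle ~= daily trapezoid
  cfg1 <- clean_cfg(n_fert_events = 1, n_rain_events = 0,
                    pulse_amplitude = 2.5, pulse_decay_days = 6)
  cal1 <- generate_event_calendar(cfg1)
  tr1 <- generate_true_flux_field(cfg1, generate_soil_profiles(cfg1), cal1)
  L <- as.numeric(cfg1$period_end - cfg1$period_start)
  K <- as.numeric(cfg1$period_end - cal1$date[1])
  closed <- 0.24 * (10 * L + 2.5 * 10 * 6 * (1 - exp(-K / 6)))
  quad <- integrate(function(u) {
    e <- as.numeric(cal1$date[1] - cfg1$period_start)
    10 + ifelse(u >= e, 25 * exp(-(u - e) / 6), 0)
  }, 0, L, subdivisions = 2000L, rel.tol = 1e-10)$value * 0.24
  expect_equal(closed, quad, tolerance = 1e-6)
  # daily trapezoid of the sampled pulse: exact geometric series, with the
  # onset ramp [e-1, e] contributing half the peak
  q <- exp(-1 / 6)
  pulse_trapz <- 25 * ((1 - q^(K + 1)) / (1 - q) - 0.5 * q^K)
  discrete <- 0.24 * (10 * L + pulse_trapz)
  expect_equal(tr1$summary$true_cumulative[1], discrete, tolerance = 1e-9)
  # ... and agrees with the continuous closed form to discretisation error
  expect_equal(tr1$summary$true_cumulative[1], closed, tolerance = 0.02)

  # events outside the period are rejected
  bad <- data.frame(date = cfg1$period_end + 30, kind = "rain",
                    magnitude = 30)
  expect_error(generate_true_flux_field(cfg1,
                                        generate_soil_profiles(cfg1), bad),
               "outside")
})

test_that("noiseless sampled closures invert to the exact truth (round trip)", {
  cfg <- clean_cfg()
  prof <- generate_soil_profiles(cfg)
  cal <- generate_event_calendar(cfg)
  truth <- generate_true_flux_field(cfg, prof, cal)
  sched <- seq(cfg$period_start, cfg$period_end, by = "day")
  clo <- sample_campaign(truth, sched, cfg)
  expect_identical(clo, sample_campaign(truth, sched, cfg))
  expect_equal(sort(unique(clo$t_min)), c(0, 20, 40, 60))

  fx <- process_closures(clo)
  expect_true(all(fx$qc_status == "ok"))
  key <- merge(fx, truth$daily,
               by = c("patch", "microplot", "date"))
  expect_equal(nrow(key), nrow(fx))
  expect_lt(max(abs(key$n2o_flux - key$true_flux) / key$true_flux), 1e-9)

  # daily sampling + zero noise: estimated share equals the truth share
  em <- summarise_emissions(fx, cal, cfg$period_start, cfg$period_end)
  cmp <- merge(em, truth$summary, by = c("patch", "microplot"))
  expect_equal(cmp$share_pct, cmp$true_share_pct, tolerance = 1e-9)
  expect_equal(cmp$cumulative, cmp$true_cumulative, tolerance = 1e-9)

  expect_error(sample_campaign(truth, as.Date(character()), cfg), "empty")
  expect_error(sample_campaign(truth, cfg$period_end + 10, cfg),
               "outside")
})

test_that("forced CO2 corruption is always flagged and noisy fluxes are unbiased", {
  cfg <- clean_cfg(corrupt_closure_rate = 1)
  prof <- generate_soil_profiles(cfg)
  cal <- generate_event_calendar(cfg)
  truth <- generate_true_flux_field(cfg, prof, cal)
  sched <- campaign_schedule(cfg, cal)
  clo <- sample_campaign(truth, sched, cfg, corrupt_modes = "co2_decrease")
  fx <- process_closures(clo)
  expect_true(all(fx$qc_status == "co2_decrease"))

  # moderate noise: mean recovered flux within 2 sd of the truth mean
  cfgn <- clean_cfg(noise_sd_conc = 0.005)
  trn <- generate_true_flux_field(cfgn, generate_soil_profiles(cfgn),
                                  generate_event_calendar(cfgn))
  schedn <- seq(cfgn$period_start, by = "day", length.out = 50)
  fxn <- process_closures(sample_campaign(trn, schedn, cfgn))
  keyn <- merge(fxn, trn$daily, by = c("patch", "microplot", "date"))
  err <- keyn$n2o_flux - keyn$true_flux
  expect_gt(nrow(keyn), 99)
  expect_lt(abs(mean(err)), 2 * sd(err) / sqrt(nrow(keyn)))
})

test_that("writing a campaign produces the expected CSV files", {
  dir <- withr::local_tempdir()
  cfg <- truth_config(n_patches = 1, microplots_per_patch = 2,
                      period_start = as.Date("2023-04-01"),
                      period_end = as.Date("2023-05-01"), seed = 2)
  out <- write_campaign(cfg, dir)
  files <- c("closures.csv", "truth.csv", "truth_summary.csv",
             "profiles.csv", "events.csv", "weather.csv", "loggers.csv")
  expect_true(all(file.exists(file.path(dir, files))))
  back <- read.csv(file.path(dir, "closures.csv"))
  expect_equal(nrow(back), nrow(out$closures))
})
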