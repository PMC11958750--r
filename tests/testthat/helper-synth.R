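# shared fixtures built in code

# small noiseless campaign configuration for exact-recovery checks
clean_cfg <- function(...) {
  args <- modifyList(
    list(n_patches = 1, microplots_per_patch = 2,
         period_start = as.Date("2023-04-01"),
         period_end = as.Date("2023-06-30"),
         noise_sd_conc = 0, corrupt_closure_rate = 0,
         sand_range = c(80, 80), seed = 11),
    list(...))
  do.call(truth_config, args)
}

# synthetic driver-analysis table: crop (categorical) and co2 are the
# designed drivers; noise1..noise4 carry no signal
make_feature_table <- function(n = 102, seed = 1, noise_sd = 1) {
  withr::with_seed(seed, {
    crop <- factor(sample(c("maize", "barley", "lupine", "oat", "wheat"),
                          n, replace = TRUE))
    crop_eff <- c(maize = 9, barley = 6, lupine = 1, oat = 2, wheat = 4)
    co2 <- runif(n, 20, 120)
    tab <- data.frame(
      crop = crop, co2 = co2,
      noise1 = rnorm(n), noise2 = runif(n), noise3 = rnorm(n, 5, 2),
      noise4 = sample(n))
    tab$response <- crop_eff[as.character(crop)] + 0.08 * co2 +
      rnorm(n, 0, noise_sd)
    tab
  })
}

# independent trapezoid + window-split oracle used against the package's
# integration (separate arithmetic path)
oracle_split <- function(flux, hot) {
  n <- length(flux)
  hotsum <- 0
  tot <- 0
  for (i in seq_len(n - 1)) {
    seg <- (flux[i] + flux[i + 1]) / 2 * 0.24
    tot <- tot + seg
    hotsum <- hotsum + seg * (hot[i] + hot[i + 1]) / 2
  }
  c(hot = hotsum, total = tot)
}
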