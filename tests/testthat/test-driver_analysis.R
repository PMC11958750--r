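test_that("feature table joins on microplot x period and derives the daily response", {
  em <- data.frame(patch = 1, microplot = 1:4, crop_period = "maize23",
                   cumulative = c(240, 480, 120, 360), period_days = 100)
  cov <- data.frame(patch = 1, microplot = 1:4, crop_period = "maize23",
                    sand = c(70, 80, 75, 90), tn = 0.08)
  tab <- build_feature_table(em, cov)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$response, c(2.4, 4.8, 1.2, 3.6))

  # a constant-flux series of f ug m-2 h-1 has daily response f * 0.24
  f <- 12.5
  s0 <- as.Date("2023-01-01")
  ser <- data.frame(date = seq(s0, s0 + 80, "day"), flux = f)
  em2 <- data.frame(patch = 1, microplot = 1, crop_period = "maize23",
                    cumulative = cumulative_emission(ser),
                    period_days = 80)
  tab2 <- build_feature_table(em2, cov[1, ])
  expect_equal(tab2$response, f * 0.24)

  cov_bad <- transform(cov, crop_period = "other")
  expect_error(build_feature_table(em, cov_bad), "empty join")

  cov_na <- cov
  cov_na$tn[2] <- NA
  expect_message(tab3 <- build_feature_table(em, cov_na), "1 rows dropped")
  expect_equal(nrow(tab3), 3)
  expect_equal(attr(tab3, "n_dropped"), 1)
})

test_that("Durbin-Watson matches hand values and white-noise behaviour", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 12 / 4)  # hand: 3
  expect_equal(durbin_watson(rep(2, 10)), 0)
  expect_warning(dw0 <- durbin_watson(rep(0, 5)), "undefined")
  expect_true(is.na(dw0))
  expect_error(durbin_watson(c(1, 2)), "3 finite")

  withr::with_seed(3, {
    e <- rnorm(1000)
    expect_gt(durbin_watson(e), 1.85)
    expect_lt(durbin_watson(e), 2.15)
  })

  # cross-check against the regression-based reference implementation
  skip_if_not_installed("lmtest")
  withr::with_seed(4, {
    d <- data.frame(x = runif(50))
    d$y <- 1 + 2 * d$x + rnorm(50, 0, 0.3)
    fit <- lm(y ~ x, d)
    expect_equal(durbin_watson(unname(fit$residuals)),
                 unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-9)
  })
})

test_that("ALE recovers linear and additive effects and is centered", {
  withr::with_seed(6, {
    d <- data.frame(x = runif(1000), z = runif(1000))
    lin <- list()  # model object unused by the predictor
    pf <- function(object, newdata) 3 * newdata$x
    a <- ale_curve(lin, d, "x", n_bins = 10, predict_fun = pf)
    fit <- lm(ale ~ x, a)
    expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.01)
    # centered to the data distribution
    expect_lt(abs(sum(a$n[-1] * (a$ale[-1] + a$ale[-nrow(a)]) / 2) /
                    sum(a$n[-1])), 1e-8)

    # unused feature: flat zero curve
    az <- ale_curve(lin, d, "z", n_bins = 10, predict_fun = pf)
    expect_lt(max(abs(az$ale)), 1e-12)

    # additive model: each ALE recovers its component up to centering
    pf2 <- function(object, newdata) 3 * newdata$x + newdata$z^2
    ax <- ale_curve(lin, d, "x", n_bins = 20, predict_fun = pf2)
    expect_equal(unname(coef(lm(ale ~ x, ax))[2]), 3, tolerance = 0.02)
    az2 <- ale_curve(lin, d, "z", n_bins = 20, predict_fun = pf2)
    # z^2 centered over U(0,1) is z^2 - 1/3
    expect_equal(az2$ale, az2$x^2 - 1 / 3, tolerance = 0.02)

    # constant feature degenerates to a flat single-bin curve
    dc <- data.frame(x = rep(1, 50))
    ac <- ale_curve(lin, dc, "x", predict_fun = pf)
    expect_equal(nrow(ac), 1)
    expect_equal(ac$ale, 0)
    expect_error(ale_curve(lin, data.frame(x = letters[1:9]), "x",
                           predict_fun = pf), "numeric")
  })
})

test_that("random-forest importance ranks an exact predictor first and books folds honestly", {
  withr::with_seed(7, {
    n <- 60
    d <- data.frame(a = runif(n), b = runif(n), c = runif(n))
    d$response <- d$a  # response is a copy of one feature
    fit <- fit_rf_with_importance(d, n_trees = 200, folds = 5, seed = 1)
    expect_equal(fit$importance$feature[1], "a")
    expect_gt(fit$importance$inc_mse_pct[1],
              3 * max(abs(fit$importance$inc_mse_pct[-1])))
    expect_gt(fit$fit_r2, 0.8)
    # fold bookkeeping: a permutation of balanced fold labels
    expect_equal(sort(unique(fit$fold_id)), 1:5)
    expect_true(all(table(fit$fold_id) == n / 5))
    expect_equal(length(fit$residuals), n)
    expect_true(fit$dw > 0 && fit$dw < 4)
    # deterministic under a fixed seed
    fit2 <- fit_rf_with_importance(d, n_trees = 200, folds = 5, seed = 1)
    expect_identical(fit$importance, fit2$importance)
    expect_identical(fit$cv, fit2$cv)
  })
  expect_error(fit_rf_with_importance(
    data.frame(a = 1:5, response = 1:5)), "at least 10")
})

test_that("pure-noise permutation importance centers on zero", {
  withr::with_seed(12, {
    vals <- replicate(20, {
      n <- 50
      d <- data.frame(a = runif(n), noise = rnorm(n))
      d$response <- d$a + rnorm(n, 0, 0.1)
      fit <- fit_rf_with_importance(d, n_trees = 150, folds = 5,
                                    seed = sample.int(1e6, 1))
      fit$importance$inc_mse_pct[fit$importance$feature == "noise"]
    })
    expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(length(vals)) + 1)
  })
})

test_that("shadow selection keeps designed drivers and rejects noise", {
  tab <- make_feature_table(n = 102, seed = 5)
  sel <- select_features_shadow(tab, n_runs = 25, n_trees = 200, seed = 2)
  expect_true(all(c("crop", "co2") %in% sel$kept))
  expect_false(any(paste0("noise", 1:4) %in% sel$kept))
  # deterministic given the seed
  sel2 <- select_features_shadow(tab, n_runs = 25, n_trees = 200, seed = 2)
  expect_identical(sel$hits, sel2$hits)

  # duplicated informative feature: both copies retained (marginal test)
  tab2 <- make_feature_table(n = 102, seed = 6)
  tab2$co2_dup <- tab2$co2
  sel3 <- select_features_shadow(tab2, n_runs = 25, n_trees = 200,
                                 seed = 3)
  expect_true(all(c("co2", "co2_dup") %in% sel3$kept))

  # constant response: nothing is relevant
  tab3 <- make_feature_table(n = 40, seed = 7)
  tab3$response <- 5
  sel4 <- select_features_shadow(tab3, n_runs = 5, n_trees = 100, seed = 4)
  expect_equal(sel4$kept, character(0))
})

test_that("correlations match the covariance formula and flag degenerate inputs", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 7))
  r <- microplot_correlations(d, "y", "x")
  # hand Pearson: cov / (sd sd)
  num <- sum((d$x - 3) * (d$y - mean(d$y)))
  den <- sqrt(sum((d$x - 3)^2) * sum((d$y - mean(d$y))^2))
  expect_equal(r$r, num / den, tolerance = 1e-12)
  expect_equal(r$p_value, cor.test(d$x, d$y)$p.value)

  ident <- microplot_correlations(data.frame(x = 1:10, y = 1:10), "y", "x")
  expect_equal(ident$r, 1)

  withr::with_seed(9, {
    ok <- replicate(40, {
      d2 <- data.frame(x = rnorm(100), y = rnorm(100))
      abs(microplot_correlations(d2, "y", "x")$r) < 0.3
    })
    expect_gte(mean(ok), 0.95)
  })

  dz <- data.frame(x = rep(1, 6), y = rnorm(6))
  rz <- microplot_correlations(dz, "y", "x")
  expect_false(rz$defined)
  expect_error(microplot_correlations(data.frame(x = 1:3, y = 1:3),
                                      "y", "x"), "4 paired")
})

test_that("rank-sum comparison wraps the exact test", {
  x <- c(444, 380, 510, 402)
  y <- c(640, 820, 455, 712)
  r <- compare_groups_wilcoxon(x, y)
  ref <- wilcox.test(x, y)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p.value, ref$p.value)
  expect_equal(r$mean_x, mean(x))
})
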