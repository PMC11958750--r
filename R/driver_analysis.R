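## driver_analysis: rank the drivers of mean daily N2O emission with a
## regression random forest — permutation importance (%IncMSE), tenfold
## cross-validation, a Durbin-Watson residual check, accumulated local
## effect curves, and simple microplot-scale correlations.

#' Assemble the feature table for the driver analysis
#'
#' Inner join of per-microplot cumulative emissions and period covariates
#' on microplot x crop period; the response is the mean daily emission
#' (cumulative divided by period length in days). Rows with missing
#' features are dropped with a message.
#'
#' @param emissions Data frame with `patch`, `microplot`, `crop_period`,
#'   `cumulative` (g N2O-N ha^-1) and `period_days`.
#' @param covariates Data frame keyed by `patch`, `microplot`,
#'   `crop_period` with feature columns.
#' @return Data frame with `response` (g N2O-N ha^-1 d^-1), key columns
#'   and all covariate columns; attribute `n_dropped` records removals.
#' @export
build_feature_table <- function(emissions, covariates) {
  key <- c("patch", "microplot", "crop_period")
  stopifnot(all(c(key, "cumulative", "period_days") %in% names(emissions)),
            all(key %in% names(covariates)))
  tab <- merge(emissions, covariates, by = key)
  if (nrow(tab) == 0) stop("empty join: no matching microplot x period keys")
  tab$response <- tab$cumulative / tab$period_days
  feat <- setdiff(names(tab), c(key, "cumulative", "period_days",
                                "response"))
  complete <- stats::complete.cases(tab[, c("response", feat)])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " rows dropped for missing features")
  }
  out <- tab[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

## forest importance for selection runs: native OOB permutation importance
.rf_importance <- function(x, y, n_trees) {
  rf <- randomForest::randomForest(x, y, ntree = n_trees,
                                   importance = TRUE)
  randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
}

#' Shadow-feature all-relevant selection
#'
#' Appends a shuffled ("shadow") copy of every feature, fits a random
#' forest, and scores a hit when a real feature's permutation importance
#' exceeds the maximum shadow importance. Over `n_runs` independent
#' shuffles, features with significantly more hits than a fair coin
#' (one-sided binomial test against p = 0.5 at `alpha`, the convention of
#' the established all-relevant shadow algorithm) are kept.
#'
#' @param data Feature table (see [build_feature_table()]).
#' @param response Name of the response column (default `"response"`).
#' @param features Feature column names (default: all others).
#' @param n_runs Number of shuffle-and-fit runs (>= 20 recommended).
#' @param n_trees Trees per forest (default 300).
#' @param alpha Significance level of the binomial test (default 0.05).
#' @param seed Integer seed; results are deterministic given it.
#' @return List: `kept`, `rejected`, `hits` (named counts), `n_runs`,
#'   `p_values`.
#' @export
select_features_shadow <- function(data, response = "response",
                                   features = NULL, n_runs = 30,
                                   n_trees = 300, alpha = 0.05,
                                   seed = 1) {
  if (is.null(features)) {
    features <- setdiff(names(data), c(response, "patch", "microplot",
                                       "crop_period", "cumulative",
                                       "period_days"))
  }
  stopifnot(length(features) >= 2, n_runs >= 1)
  y <- data[[response]]
  x <- data[features]
  x[] <- lapply(x, function(v) if (is.character(v)) factor(v) else v)
  if (var(y) == 0) {
    return(list(kept = character(0), rejected = features,
                hits = setNames(rep(0L, length(features)), features),
                n_runs = n_runs, p_values = setNames(
                  rep(1, length(features)), features)))
  }
  hits <- setNames(rep(0L, length(features)), features)
  .with_seed(seed, {
    for (run in seq_len(n_runs)) {
      shadow <- x[sample(nrow(x)), , drop = FALSE]
      names(shadow) <- paste0("shadow_", features)
      rownames(shadow) <- NULL
      imp <- .rf_importance(cbind(x, shadow), y, n_trees)
      max_shadow <- max(imp[paste0("shadow_", features)])
      hits <- hits + (imp[features] > max_shadow)
    }
  })
  p0 <- 0.5
  p_values <- vapply(hits, function(h) {
    binom.test(h, n_runs, p = p0, alternative = "greater")$p.value
  }, numeric(1))
  kept <- features[p_values < alpha]
  list(kept = kept, rejected = setdiff(features, kept), hits = hits,
       n_runs = n_runs, p_values = p_values)
}

#' Random forest fit with permutation importance and cross-validation
#'
#' Fits a regression random forest and reports, per feature, the
#' percentage increase in mean squared error when that feature's values
#' are permuted (`%IncMSE = 100 * (MSE_perm - MSE_base) / MSE_base`,
#' averaged over `n_perm` permutations), the full-data fit R2, the
#' out-of-bag variance explained, tenfold cross-validated R2 / RMSE / MAE
#' (held-out folds only), and the Durbin-Watson statistic of the
#' row-ordered residuals.
#'
#' @param data Feature table.
#' @param response Response column name (default `"response"`).
#' @param features Feature columns (default: all others).
#' @param n_trees Trees (default 500).
#' @param n_perm Permutation repetitions per feature (default 10).
#' @param folds Cross-validation folds (default 10); data must have at
#'   least 10 rows.
#' @param seed Integer seed.
#' @return List: `model`, `importance` (data frame `feature`,
#'   `inc_mse_pct`, sorted), `fit_r2`, `oob_var_explained`, `cv`
#'   (`r2`, `rmse`, `mae`), `dw`, `fold_id`, `residuals`.
#' @export
fit_rf_with_importance <- function(data, response = "response",
                                   features = NULL, n_trees = 500,
                                   n_perm = 10, folds = 10, seed = 1) {
  if (is.null(features)) {
    features <- setdiff(names(data), c(response, "patch", "microplot",
                                       "crop_period", "cumulative",
                                       "period_days"))
  }
  y <- data[[response]]
  n <- length(y)
  if (n < 10) stop("need at least 10 rows for cross-validation")
  x <- data[features]
  x[] <- lapply(x, function(v) if (is.character(v)) factor(v) else v)
  .with_seed(seed, {
    rf <- randomForest::randomForest(x, y, ntree = n_trees,
                                     keep.inbag = TRUE)
    pred <- predict(rf, x)
    sst <- sum((y - mean(y))^2)
    fit_r2 <- 1 - sum((y - pred)^2) / sst
    ## permutation importance on out-of-bag predictions: resubstitution
    ## MSE is near zero for a forest, which would inflate the ratio
    oob <- rf$inbag == 0
    seen <- rowSums(oob) > 0
    oob_mse <- function(ind) {
      agg <- rowSums(ind * oob)[seen] / rowSums(oob)[seen]
      mean((y[seen] - agg)^2)
    }
    mse_base <- oob_mse(predict(rf, x, predict.all = TRUE)$individual)
    imp <- vapply(features, function(f) {
      mean(vapply(seq_len(n_perm), function(r) {
        xp <- x
        xp[[f]] <- xp[[f]][sample(n)]
        msep <- oob_mse(predict(rf, xp, predict.all = TRUE)$individual)
        100 * (msep - mse_base) / mse_base
      }, numeric(1)))
    }, numeric(1))
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    cv_pred <- rep(NA_real_, n)
    for (k in seq_len(folds)) {
      test <- fold_id == k
      rf_k <- randomForest::randomForest(x[!test, , drop = FALSE],
                                         y[!test], ntree = n_trees)
      cv_pred[test] <- predict(rf_k, x[test, , drop = FALSE])
    }
    res <- y - pred
    imp_df <- data.frame(feature = names(imp),
                         inc_mse_pct = unname(imp))
    imp_df <- imp_df[order(-imp_df$inc_mse_pct), ]
    rownames(imp_df) <- NULL
    list(model = rf, importance = imp_df, fit_r2 = fit_r2,
         oob_var_explained = 100 * (1 - rf$mse[n_trees] / var(y)),
         cv = list(r2 = 1 - sum((y - cv_pred)^2) / sst,
                   rmse = sqrt(mean((y - cv_pred)^2)),
                   mae = mean(abs(y - cv_pred))),
         dw = durbin_watson(res), fold_id = fold_id, residuals = res)
  })
}

#' Durbin-Watson statistic
#'
#' `DW = sum((e_t - e_(t-1))^2) / sum(e_t^2)` over residuals in their
#' given (temporal) order; values near 2 indicate no first-order
#' autocorrelation.
#'
#' @param residuals Numeric residuals, >= 3 finite values, in time order.
#' @return The DW statistic (in (0, 4)); `NA` with a warning for all-zero
#'   residuals.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 3 || any(!is.finite(residuals))) {
    stop("need >= 3 finite residuals")
  }
  denom <- sum(residuals^2)
  if (denom == 0) {
    warning("all-zero residuals: DW undefined")
    return(NA_real_)
  }
  sum(diff(residuals)^2) / denom
}

#' Accumulated local effects of one numeric feature
#'
#' Classic ALE: feature values are cut at quantile bin edges; within each
#' bin the mean prediction difference between substituting the upper and
#' lower edge is accumulated cumulatively, then the curve is centered by
#' subtracting its data-weighted mean, so effects average to zero over the
#' observed distribution. ALE is preferred over partial dependence when
#' features are correlated, since only local substitutions are evaluated.
#'
#' @param object Fitted model passed to `predict_fun`.
#' @param data Data frame of predictor rows used to localise effects.
#' @param feature Name of a numeric feature.
#' @param n_bins Number of quantile bins (>= 2, default 10).
#' @param predict_fun Function `(object, newdata) -> numeric`; defaults
#'   to [stats::predict()].
#' @return Data frame of class `"ale_curve"`: `x` (bin edges including
#'   the minimum), `ale` (centered effect at each edge), `n` (rows per
#'   bin, 0 for the first edge).
#' @export
ale_curve <- function(object, data, feature, n_bins = 10,
                      predict_fun = NULL) {
  stopifnot(feature %in% names(data), n_bins >= 2)
  xv <- data[[feature]]
  if (!is.numeric(xv)) stop("ALE implemented for numeric features only")
  if (is.null(predict_fun)) {
    predict_fun <- function(object, newdata) predict(object, newdata)
  }
  edges <- unique(quantile(xv, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7))
  if (length(edges) < 2) {
    ## constant feature: single degenerate bin, flat curve
    out <- data.frame(x = edges[1], ale = 0, n = length(xv))
    class(out) <- c("ale_curve", "data.frame")
    return(out)
  }
  k <- length(edges) - 1
  bin <- cut(xv, edges, include.lowest = TRUE, labels = FALSE)
  d <- numeric(k)
  n_bin <- integer(k)
  for (j in seq_len(k)) {
    rows <- which(bin == j)
    n_bin[j] <- length(rows)
    if (length(rows) == 0) next
    lo <- data[rows, , drop = FALSE]
    hi <- lo
    lo[[feature]] <- edges[j]
    hi[[feature]] <- edges[j + 1]
    d[j] <- mean(predict_fun(object, hi) - predict_fun(object, lo))
  }
  g <- c(0, cumsum(d))
  ## center with bin-interval midpoints weighted by occupancy
  center <- sum(n_bin * (g[-1] + g[-length(g)]) / 2) / sum(n_bin)
  out <- data.frame(x = edges, ale = g - center, n = c(0L, n_bin))
  class(out) <- c("ale_curve", "data.frame")
  out
}

#' Pearson correlations of emissions with soil/environment variables
#'
#' Per variable, the Pearson correlation of the response with paired
#' finite observations, plus the two-sided p-value. Zero-variance
#' variables are flagged undefined.
#'
#' @param data Data frame holding the response and variables.
#' @param response Response column name.
#' @param variables Variable names (default: all numeric others).
#' @return Data frame: `variable`, `n`, `r`, `p_value`, `defined`.
#' @export
microplot_correlations <- function(data, response,
                                   variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                         response)
  }
  y <- data[[response]]
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4) stop("need >= 4 paired observations for ", v)
    if (var(x[ok]) == 0 || var(y[ok]) == 0) {
      return(data.frame(variable = v, n = sum(ok), r = NA_real_,
                        p_value = NA_real_, defined = FALSE))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(variable = v, n = sum(ok), r = unname(ct$estimate),
               p_value = ct$p.value, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum comparison of two emission groups
#'
#' Thin wrapper around the exact rank-sum test (used e.g. to compare
#' study years), reporting the statistic, p-value and group means/sds.
#'
#' @param x,y Numeric samples (e.g. crop cumulatives per year).
#' @return List: `statistic`, `p.value`, `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y`.
#' @export
compare_groups_wilcoxon <- function(x, y) {
  wt <- wilcox.test(x, y)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       mean_x = mean(x), mean_y = mean(y), sd_x = sd(x), sd_y = sd(y))
}
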