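## heterogeneity: spatial variability of cumulative emissions within and
## between patches (coefficient of variation, Levene's test, CV ~ sand).

#' Coefficient of variation
#'
#' `CV (%) = 100 * sd / mean` with the sample (n - 1) standard deviation.
#' The CV is undefined (returned `NA`, flagged) for non-positive means.
#'
#' @param values Numeric vector, n >= 2.
#' @param group Optional label carried into the result.
#' @return One-row data frame: `group`, `n`, `mean`, `sd`, `cv` (percent),
#'   `cv_defined`.
#' @examples
#' cv(c(1, 2, 3))  # cv = 50
#' @export
cv <- function(values, group = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("CV needs at least 2 finite values")
  m <- mean(values)
  s <- sd(values)
  data.frame(group = group, n = length(values), mean = m, sd = s,
             cv = if (m > 0) 100 * s / m else NA_real_,
             cv_defined = m > 0)
}

#' Within-patch and between-patch CV of cumulative emissions
#'
#' Within-patch CVs are computed over each patch's microplot cumulatives;
#' the between-patch CV over the patch mean cumulatives (one value per
#' patch).
#'
#' @param emissions Data frame with columns `patch`, and the value column
#'   named by `value_col` (default `"cumulative"`).
#' @param value_col Name of the value column.
#' @return Data frame of [cv()] rows: one per patch plus one
#'   `"between-patches"` row.
#' @export
within_between_cv <- function(emissions, value_col = "cumulative") {
  stopifnot(all(c("patch", value_col) %in% names(emissions)))
  vals <- emissions[[value_col]]
  per_patch <- lapply(split(vals, emissions$patch), function(v) v)
  if (length(per_patch) < 2) stop("need >= 2 patches")
  if (any(vapply(per_patch, length, 1L) < 2)) {
    stop("need >= 2 microplots per patch")
  }
  rows <- mapply(function(v, g) cv(v, group = g),
                 per_patch, names(per_patch), SIMPLIFY = FALSE)
  means <- vapply(per_patch, mean, numeric(1))
  out <- rbind(do.call(rbind, rows), cv(means, group = "between-patches"))
  rownames(out) <- NULL
  out
}

#' Levene's test for homogeneity of variance across groups
#'
#' One-way ANOVA on absolute deviations from the group center: the
#' median-centered Brown-Forsythe variant by default (the default of the
#' reference R implementation, and better calibrated at small group
#' sizes), or the classic mean-centered statistic with `center = "mean"`.
#' Degenerate all-equal groups give statistic 0 and p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length.
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"`
#'   (classic).
#' @return List: `statistic`, `df` (length 2), `p.value`.
#' @export
levene_homogeneity <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
  cfun <- if (center == "mean") mean else median
  centers <- tapply(values, groups, cfun)
  z <- abs(values - centers[as.integer(groups)])
  if (all(z == 0) || var(z) == 0) {
    return(list(statistic = 0,
                df = c(nlevels(groups) - 1L,
                       length(values) - nlevels(groups)),
                p.value = 1))
  }
  fit <- anova(lm(z ~ groups))
  list(statistic = fit[["F value"]][1],
       df = c(fit$Df[1], fit$Df[2]),
       p.value = fit[["Pr(>F)"]][1])
}

#' Regression of within-patch CV on patch sand content
#'
#' Simple OLS of the within-patch CV (%) on the patch mean sand content
#' (%), summarising whether sandier patches are spatially more variable.
#'
#' @param cvs Within-patch CVs, percent (>= 3 patches).
#' @param sand Patch mean sand contents, percent, same length.
#' @return List: `slope`, `intercept`, `r2`.
#' @export
cv_vs_sand <- function(cvs, sand) {
  stopifnot(length(cvs) == length(sand))
  ok <- is.finite(cvs) & is.finite(sand)
  if (sum(ok) < 3) stop("need >= 3 patches with defined CV")
  fit <- lm(cvs[ok] ~ sand[ok])
  sst <- sum((cvs[ok] - mean(cvs[ok]))^2)
  sse <- sum(fit$residuals^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = if (sst > 0) 1 - sse / sst else NA_real_)
}
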