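#!/usr/bin/env Rscript
# Spatial heterogeneity of cumulative emissions: CV within each patch and
# between patch means, Levene homogeneity of variance, and the regression
# of within-patch CV on patch sand content.
# Writes results/heterogeneity.csv.

library(patchflux)

em <- read.csv("results/emissions.csv")
prof <- read.csv("results/campaign/profiles.csv")

cvs <- within_between_cv(em)
write.csv(cvs, "results/heterogeneity.csv", row.names = FALSE)
cat("Coefficients of variation (%):\n")
print(cvs[, c("group", "n", "mean", "cv")], digits = 3)

lev <- levene_homogeneity(em$cumulative, em$patch)
cat(sprintf("Levene (Brown-Forsythe) across patches: F(%d,%d) = %.2f, p = %.4f\n",
            lev$df[1], lev$df[2], lev$statistic, lev$p.value))

within <- cvs[cvs$group != "between-patches", ]
sand <- tapply(prof$sand, prof$patch, mean)[within$group]
fit <- cv_vs_sand(within$cv, sand)
cat(sprintf("CV ~ sand: slope %.2f %%CV per %%sand, R2 = %.2f\n",
            fit$slope, fit$r2))
yc <- tapply(prof$yield_class, prof$patch, function(x) x[1])[within$group]
cat(sprintf("mean within-patch CV: high yield %.1f%%, low yield %.1f%%\n",
            mean(within$cv[yc == "high"]), mean(within$cv[yc == "low"])))
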