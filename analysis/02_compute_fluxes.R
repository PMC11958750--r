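#!/usr/bin/env Rscript
# Chamber closures -> QC'd N2O and CO2 fluxes: per-closure OLS slopes,
# 6 x IQR outlier screening against the campaign-pooled residual band,
# the CO2 plausibility check, and the ideal-gas flux conversion.
# Reads results/campaign/closures.csv, writes results/fluxes.csv.

library(patchflux)

closures <- read.csv("results/campaign/closures.csv")
fluxes <- process_closures(closures)
write.csv(fluxes, "results/fluxes.csv", row.names = FALSE)

cat("QC outcome over", nrow(fluxes), "closures:\n")
print(table(fluxes$qc_status))
cat(sprintf("outlier points removed: %d (N2O), %d (CO2)\n",
            sum(fluxes$points_removed_n2o, na.rm = TRUE),
            sum(fluxes$points_removed_co2, na.rm = TRUE)))
ok <- fluxes[fluxes$qc_status == "ok", ]
cat(sprintf("N2O flux range: %.1f .. %.1f ug N2O-N m-2 h-1 (median %.1f)\n",
            min(ok$n2o_flux), max(ok$n2o_flux), median(ok$n2o_flux)))

# against the generator truth, where known
truth <- read.csv("results/campaign/truth.csv")
truth$date <- as.Date(truth$date)
key <- merge(ok, truth, by = c("patch", "microplot", "date"))
cat(sprintf("flux recovery: median |error| %.2f ug m-2 h-1 over %d clean closures\n",
            median(abs(key$n2o_flux - key$true_flux)), nrow(key)))
cat("Fluxes written to results/fluxes.csv\n")
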