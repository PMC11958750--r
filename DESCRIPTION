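Package: patchflux
Title: Chamber-Based N2O Flux Processing, Hot-Moment Attribution and
    Spatial Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes static closed-chamber greenhouse-gas measurements
    from patch-scale agricultural monitoring into quality-controlled N2O
    and CO2 fluxes (ideal-gas slope method with CO2-based plausibility
    screening and interquartile-range outlier removal), interpolates
    campaign fluxes to daily series and cumulative crop-period emissions,
    attributes emissions to event-driven hot moments (14 days after
    fertilization, 7 days after heavy rain), derives soil and microclimate
    covariates (water-filled pore space, silt-plus-clay to sand ratio,
    transect slope), quantifies within- and between-patch heterogeneity
    (coefficient of variation, Levene's test), and ranks emission drivers
    with a random forest (permutation importance, tenfold cross-validation,
    accumulated local effects). Includes a synthetic campaign generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    lmtest,
    jsonlite
Config/testthat/edition: 3
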