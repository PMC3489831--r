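Package: tundrasel
Title: Two-Scale Resource Selection Analysis for Arctic Caribou Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating summer resource selection
    by barren-ground caribou at two spatial scales from GPS collar data and
    environmental rasters. Provides GPS fix screening (2D fixes, PDOP,
    sedentary bouts), biological season partitioning, temperature/wind insect
    activity indices, raster covariate engineering (moving-window vegetation
    densities with TTLQV scale selection, vector ruggedness, NDVI phenology
    dates, distance to coast), kernel-density range isopleths, used-available
    sampling at the landscape (1:1 within the 95% isopleth) and patch (5:1
    matched steps) scales, random-intercept logistic and conditional logistic
    model fitting with all-subsets AIC selection, autocorrelation-robust
    standard errors via split-sample refitting, Boyce-style k-fold cross
    validation, and relative-probability-of-use mapping. A synthetic-data
    module generates landscapes, weather series and movement tracks with
    known selection coefficients for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    mgcv,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
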