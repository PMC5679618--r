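Package: pondpredict
Title: Environmental Predictability of Ponds from Multispectral Time Series
Version: 0.1.0
Authors@R: person("pondpredict", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the environmental predictability of ponds and shallow
    lakes from long multispectral satellite image time series. Implements a
    two-condition water/salt pixel classification (MNDWI water candidacy with
    a near-infrared salt-crust filter), water-surface-area time-series
    construction with cloud-uncertainty bookkeeping, Colwell's
    constancy/contingency/predictability on five discrete state models, a
    continuous spline-regression predictability index based on seasonal GAM
    residuals, and a model-comparison stage (Pearson correlation, chord
    distance, UPGMA clustering with bootstrap support). Includes a synthetic
    scene and time-series generator with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    sp,
    mgcv,
    stats,
    utils,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
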