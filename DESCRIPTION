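Package: geocv
Title: Spatial Cross-Validation Diagnostics for Geospatial Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how spatial autocorrelation inflates random
    cross-validation statistics of geospatial prediction models such as
    1-km forest aboveground-biomass maps. Provides spatially blocked
    K-fold cross-validation via complete-linkage clustering, buffered
    leave-one-out cross-validation with an extrapolation safeguard,
    null and coordinates-only baseline models, empirical semivariogram
    diagnostics with autocorrelation-range estimation, a pixel
    quality-filter chain, derived climate and spectral covariates
    (water availability, maximal climate water deficit, dry-season
    statistics, EVI2, NDII), and a Gaussian-random-field scenario
    generator that emulates clustered tropical forest-inventory
    sampling so the full validation pipeline can be exercised on
    synthetic landscapes with known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
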