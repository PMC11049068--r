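Package: nirquant
Title: Near-Infrared Spectroscopy Calibration with PLS and Wavelength Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics toolkit for quantifying metabolite concentrations
    from near-infrared (NIR) absorbance spectra. Provides composable spectral
    pretreatments (moving-window smoothing, gap derivatives, multiplicative
    scatter correction, standard normal variate), Mahalanobis-distance outlier
    screening in a principal-component score space, Kennard-Stone sample
    partitioning, a NIPALS PLS1 regression core with leave-one-out
    cross-validation, two wavelength-selection algorithms (uninformative
    variable elimination and competitive adaptive reweighted sampling), model
    evaluation metrics (R-squared, RMSEC/RMSEP/RMSECV, residual predictive
    deviation), an end-to-end experiment driver, and a seeded synthetic NIR
    spectra generator with known ground truth for validating every stage.
    Data-frame in, tibble out; fitted objects support tidy(), glance() and
    autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
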