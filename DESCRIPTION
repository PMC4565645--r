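Package: urbansami
Title: Scale-Adjusted Metrics for the Evolution of Urban Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scale-adjusted analysis of city-level indicator panels.
    Fits power-law allometries between urban indicators and city population by
    orthogonal-distance (Deming/major-axis) regression, computes scale-adjusted
    metrics as log-residuals from the fitted laws, tracks group means of cities
    above and below the law with bootstrap confidence intervals, models the
    one-lag memory of the residuals together with its continuous-time solution
    and residual diagnostics, fits cross-indicator linear models to forecast
    the next census, and renders the predicted changes as GeoJSON bubble maps.
    Includes a synthetic census-panel generator with known ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    goftest,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    nortest,
    readxl
Config/testthat/edition: 3
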