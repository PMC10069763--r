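Package: edmforecast
Title: Interpretable Simplex-Projection Forecasting with Shaded Forecast Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Empirical dynamic modeling (EDM) forecasting for univariate,
    evenly spaced time series. Reconstructs system state by time-delay
    embedding, finds the nearest dynamic neighbors of the current state,
    weights them by exponentially decaying distance, and forms simplex
    point forecasts as the normalized weighted mean of the neighbors'
    future trajectories. Distributional forecasts are built by summing
    weight-scaled Gaussian kernels over the neighbors' futures at each
    horizon step ("shaded forecast area") and rendered as opacity
    gradients on a static four-panel dashboard. Includes CSV/JSON
    readers and exporters, a seasonal mortality-like synthetic data
    generator, and a rolling-origin evaluator with naive benchmarks and
    CRPS scoring of the predictive density.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
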