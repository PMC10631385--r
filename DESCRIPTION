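Package: wmfpca
Title: Weighted Multivariate Functional Principal Component Models for
    Multipopulation Mortality Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling and forecasting of age-specific mortality for
    several related subpopulations using weighted multivariate functional
    principal component analysis (wMFPCA) and its coherent variant.  Log
    central death rates are smoothed with penalised regression splines under
    a partial monotonicity constraint, decomposed with geometrically
    down-weighted functional principal components estimated jointly across
    subpopulations, and extrapolated with automatically selected ARIMA models
    (stationarity-restricted ARMA for the deviation components of the
    coherent model, which keeps long-run forecasts of related subpopulations
    from diverging).  Includes a synthetic-data generator with known ground
    truth, rolling-window forecast evaluation, weight tuning, period life
    expectancy, and readers for Human Mortality Database 1x1 rate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils
Suggests:
    mgcv,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
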