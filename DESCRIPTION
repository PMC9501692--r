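Package: fardl
Title: Fourier Bootstrap ARDL Cointegration and Causality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Small-sample cointegration and causality analysis for annual
    macro-health time series (log GDP per capita, log health expenditure
    per capita, employment rate). Implements the bootstrap autoregressive
    distributed lag (ARDL) bounds test with a single-frequency Fourier
    approximation of smooth structural breaks: descriptive and
    Jarque-Bera normality statistics, DF/ADF/Phillips-Perron unit-root
    pre-tests with MacKinnon response-surface p-values, SSR-minimizing
    structural-break location, Fourier frequency and lag-order selection,
    residual-bootstrap critical values with degenerate-case
    classification, and long-run and short-run Granger causality tests.
    Ships a synthetic-data generator so the full pipeline is exercisable
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
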