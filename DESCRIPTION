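Package: didbench
Title: Monte Carlo Benchmarking of Difference-in-Differences Estimators for State-Year Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates balanced state-by-year mortality panels with known
    injected policy effects and benchmarks difference-in-differences style
    estimators against them: classic two-way fixed effects, detrended models
    with state-specific linear slopes, autoregressive lagged-outcome models
    with change-coded policy terms, and linear GEE with an AR(1) working
    correlation. Models are crossed with link functions (linear, log-linear,
    Poisson, negative binomial), population weighting or offsets, and
    standard-error estimators (model-based, Huber/HC1, cluster-robust/CR1).
    Performance is summarised by directional bias, magnitude bias, root mean
    squared error, Type I error, and calibrated correct-rejection rates.
    Includes a synthetic baseline generator emulating right-skewed,
    autocorrelated, overdispersed state mortality rates so the full pipeline
    runs without restricted vital-statistics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    sandwich,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
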