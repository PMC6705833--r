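Package: viewspike
Title: Seasonal Hybrid ESD Detection of Outlying Wikipedia Pageview Epochs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for infodemiology analyses of daily Wikipedia pageview
    traffic. Reads Langviews- and Massviews-style pageview exports, aggregates
    multi-language panels to univariate daily totals, and detects significantly
    outlying days with a Seasonal Hybrid Extreme Studentized Deviate (S-H-ESD)
    procedure: robust additive decomposition (periodic weekday seasonal
    component plus a piecewise-median trend) followed by a median/MAD
    generalized ESD test, with a Breusch-Pagan residual diagnostic. Consecutive
    outlying days are merged into ranked epochs with media-correlate search
    windows. Wikimedia clickstream referrer-resource dumps can be parsed,
    merged across months, categorized, and exported as conservation-checked
    Sankey flow documents. A synthetic-data generator produces pageview panels
    and clickstream files with known ground truth so every pipeline stage is
    testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
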