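Package: shelfkin
Title: Accelerated Shelf-Life Testing Kinetics for Stored Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accelerated shelf-life testing (ASLT) of stored food
    products. Fits zero- and first-order quality-degradation kinetics to
    storage time series, relates rate constants to temperature through the
    Arrhenius equation, predicts shelf life against a consumer-rejection
    threshold, determines experimental shelf life from censored sensory
    panel series, and simulates hedonic-panel storage studies. Ships the
    digitized storage-study tables for intermediate-moisture longan as
    worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
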