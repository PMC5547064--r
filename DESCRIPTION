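Package: humidheat
Title: Humid Heat Wave Hazard Indices from Daily Temperature and Humidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and magnitude scoring of heat waves from daily maximum
    temperature and daily minimum relative humidity. Implements the NOAA
    apparent-temperature (heat index) regression with its piecewise
    adjustments, calendar-day percentile threshold climatologies, the Heat
    Wave Magnitude Index daily (HWMId) and its humidity-aware counterpart
    (the Apparent Heat Wave Index, AHWI), the Warm Spell Duration Index,
    apparent-temperature peak danger flags, an ETCCDI-style in-base bootstrap
    bias correction, warming-level selection of model years from global-mean
    temperature anomalies with empirical exceedance probabilities, a
    reproducible synthetic daily weather and GMST generator, and plain-text
    grid I/O with bilinear regridding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
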