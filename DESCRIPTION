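Package: waagree
Title: Agreement Between Proximity-Based Well-Activity Exposure Metrics and
    Air Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess how well proximity-based "well activity" (WA)
    exposure surrogates for unconventional oil and gas development agree with
    measured air-pollutant concentrations. Implements daily development-phase
    assignment for unconventional wells (pad preparation, drilling, fracturing,
    production), the four inverse-distance-squared WA metrics evaluated at
    receptor coordinates, daily and rolling pollutant summaries (including MDA8
    ozone), pooled quartile exposure classification, and weighted-kappa /
    cross-tabulation agreement analysis with buffer-radius and rolling-average
    sensitivity analyses. A seeded synthetic-data generator produces well
    fleets, receptors and concentration series with controllable coupling so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
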