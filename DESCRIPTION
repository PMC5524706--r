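Package: hornetspread
Title: Stochastic Spatial Spread and Risk Mapping for Asian Hornet Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the establishment and spread of the yellow-legged
    (Asian) hornet Vespa velutina across a gridded landscape. Annual nest
    reproduction is Poisson with a mean shaped by a linear latitude cline,
    local density-dependent competition and habitat suitability; new queens
    disperse with exponentially distributed distances and settle
    preferentially in urban and agricultural terrain. The package provides a
    replicate simulation engine with invasion-front (wave-speed) estimation
    and dispersal calibration, detection-and-destruction control experiments
    (eradication probability, time to colonisation under repeated
    introductions), and deterministic risk-map calculations: founder-location
    posterior from sightings, expected-nest intensity fields, high-risk
    contours and branching-process extinction probabilities. A synthetic
    coastal landscape generator allows every analysis to run without external
    raster data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
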