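Package: paddywf
Title: Water Footprint and Drought Resilience of Paddy Irrigation-Drainage Units
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Daily water-quantity and water-quality simulation of paddy
    irrigation-drainage units (rice fields, ditches and small ponds) under
    four management styles, from totally centralized remote-freshwater
    irrigation to quasi-decentralized recycling of drainage water stored in
    small water bodies. Includes a monsoonal stochastic weather generator,
    FAO-56 Penman-Monteith reference evapotranspiration, CROPWAT-style
    stage-wise yield response to water stress, nutrient-spiraling retention
    of nitrogen and phosphorus in ditches and ponds with Monte-Carlo
    parameter uncertainty, green/blue/gray water-footprint and
    irrigation-self-sufficiency accounting, dry-year freshwater restriction,
    and a recycling-irrigation / pond-reconnection / pond-construction
    redesign scenario ladder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
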