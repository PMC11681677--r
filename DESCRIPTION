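Package: hesd
Title: System Dynamics Forecasting of Health Expenditure Under Demographic Ageing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stock-flow (system dynamics) simulation of national total health
    expenditure under demographic ageing. Couples a 21-age-group by sex cohort
    population projection with a workforce/GDP forecast and an age-sex indexed
    health-expenditure model, including compounding demand and cost growth,
    an efficiency-adjustment divisor, and scenario analysis over total
    fertility rate, retirement and productivity levers. Ships a synthetic
    input generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
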