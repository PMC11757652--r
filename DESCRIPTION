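Package: actinon
Title: Exhaled Rn-219 Activity Concentrations from Flow-Through Radon
    Monitor Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing direct breath measurements of Rn-219
    (actinon) exhaled by patients treated with Ra-223 dichloride.
    Converts flow-through radon-monitor readings into exhaled activity
    concentrations (calibration factor plus in-tube radioactive decay
    correction), combines paired censored recordings into one result per
    administration and time point, estimates lognormal population
    statistics from heavily right-censored data by regression on order
    statistics (q-q plot imputation), and cross-checks time points
    against published Ra-223 blood-clearance factors. Includes a
    synthetic-campaign generator for parameter-recovery studies and a
    packaged measurement-campaign fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
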