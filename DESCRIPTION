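Package: holodeb
Title: Dynamic Energy Budget Simulation of Coral Holobionts with Multiple Symbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of a coral host in symbiosis with one or
    more Symbiodiniaceae populations, built on dynamic energy budget (DEB)
    theory with synthesizing-unit kinetics. The host and symbionts exchange
    surplus carbon and nitrogen; surplus fixed carbon powers a host
    carbon-concentrating mechanism that feeds CO2 back to photosynthesis, and
    unquenched excess light drives reactive-oxygen-species production and
    bleaching. Provides flux evaluation, slow-fast (lagged-flux) Euler
    integration with healthy and bleached initializations, environmental
    survey experiments for within-host competitive dominance, rate of
    competitive exclusion and recovery from bleaching, and linear-discriminant
    summaries of survey outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
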