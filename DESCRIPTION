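Package: thawflux
Title: Carbon Emission Estimation from Thermokarst Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates lake-atmosphere carbon emission from floating-chamber
    CO2 time series and dissolved CH4 concentrations, for shallow thermokarst
    lakes surveyed across permafrost zones. Provides the physical-chemistry
    kernel (Henry solubility, Schmidt numbers, wind-based k600 models, gas
    Schmidt-number rescaling, diffusive flux), quality-controlled chamber
    slope fitting, per-lake seasonal averaging, annualization by ice-free
    days, CO2-equivalent conversion, regional upscaling with propagated
    uncertainty, comparison of chamber fluxes against wind-model fluxes, and
    a synthetic campaign generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
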