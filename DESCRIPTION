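Package: sparcsim
Title: Synchrotron Delivery-Time and Plan-Quality Simulation for Spot-Scanning Proton Arc Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the delivery of pencil-beam-scanning proton plans on a
    single-energy-extraction synchrotron accelerator. Provides a static beam
    delivery time simulator (energy-layer switch, spill, and spot-switch
    components with extra acceleration-cycle accounting), a dynamic simulator
    coupling per-control-point irradiation to gantry rotation under velocity,
    acceleration, and deceleration limits, a control-point restructuring
    procedure that converts coarse multi-field plans into one-energy-per-
    control-point arc sequences, dose-volume-histogram, conformity-index and
    integral-dose metrics, a 20-scenario worst-case robustness evaluation, and
    a synthetic phantom, plan, and toy dose generator so the whole pipeline
    runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
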