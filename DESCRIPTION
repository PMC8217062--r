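Package: lithotherm
Title: Lumped Thermal Modelling of Laser Lithotripsy in an Irrigated Vessel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic lumped-capacitance model of fluid temperature in a
    fluid-filled vessel heated by a surgical laser and cooled by irrigation
    inflow and wall losses. Provides piecewise-exponential temperature
    solutions for arbitrary laser on/off schedules, estimation of the wall
    heat-loss coefficient from thermocouple traces by least squares, the
    t43 (CEM43) thermal-dose metric, and solvers for the longest laser
    firing time that keeps the thermal dose below a damage threshold,
    together with parameter-scan tables, a synthetic-trace generator for
    validation studies, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
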