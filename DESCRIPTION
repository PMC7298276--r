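Package: hemocircuit
Title: Electrical-Analog Simulation of Splanchnic Arterial Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lumped-parameter (electrical-analog) modelling of splanchnic
    arterial blood flow. Provides a general steady-state DC resistor-network
    solver (modified nodal analysis with exact handling of zero-resistance
    shorts), two-terminal equivalent-resistance computation, bidirectional
    conversion between hemodynamic and electrical quantities
    (mmHg <-> V, L/min <-> mA), a reduced celiac-stenosis /
    pancreaticoduodenal-aneurysm circuit with a closed-form steady-flow
    oracle, quasi-static scenario simulation of the stenosis-first and
    aneurysm-first disease timelines with flow tracings and zone summaries,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
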