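Package: fieldET
Title: Field-Scale Daily Evapotranspiration from a Two-Source Energy Balance
    with Image Fusion and Canopy-Resistance Gap-Filling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates daily crop evapotranspiration (ET) at fine spatial
    resolution by fusing fine- and coarse-resolution vegetation index and
    land surface temperature imagery (a STARFM-style blend), solving the
    two-source energy balance (TSEB) with a Priestley-Taylor canopy
    temperature iteration on clear days, upscaling instantaneous fluxes to
    daily totals by the evaporative fraction, and reconstructing cloudy-day
    ET by inverting clear-day canopy resistance through the Penman-Monteith
    equation and rescaling it with leaf area index and temperature/humidity
    stress functions. Includes Jarvis-type environmental factor diagnostics,
    eddy-covariance validation utilities (Bowen-ratio closure correction,
    mean-diurnal-variation gap-filling, agreement metrics), and a seeded
    synthetic scene generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
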