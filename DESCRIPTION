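Package: memchrom
Title: Breakthrough-Curve Analysis for Membrane-Bed Chromatography
Version: 0.1.0
Authors@R:
    person("memchrom", "developers", email = "memchrom@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing dynamic protein adsorption in membrane-bed
    (and fixed-bed) chromatography from breakthrough curves. Computes the
    standard performance-indicator panel (dynamic and equilibrium binding
    capacity, mass-transfer-zone length, adsorbent exhaustion rate, bed
    utilization, productivity, residence time, permeation flux), converts
    breakthrough curves to dynamic uptake curves, fits linearized adsorption
    kinetic models (pseudo-first-order, pseudo-second-order, Elovich,
    multi-stage intraparticle diffusion), fits the Bohart-Adams, Thomas,
    Yoon-Nelson and bed-depth/service-time (BDST) breakthrough models with
    error statistics and model ranking, supports BDST scale-up across bed
    depths, and generates synthetic breakthrough curves with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
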