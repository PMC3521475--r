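Package: hemocirc
Title: Closed-Loop Lumped-Parameter Simulation of the Human Circulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A deterministic, closed-loop, lumped-parameter (0-D) simulator of
    the human circulation built on the electrical-analog tradition: compliant
    vascular compartments, Ohmic flow resistances, ideal one-way valves, two
    time-varying-elastance ventricles with a fixed 0.2 s systole, a
    respiration-driven intrathoracic pressure, and a homeostatic negative
    feedback (sympathetic modulation Sy) acting on heart rate, biventricular
    contractility and venous tone.  Ships a five-phase exercise-induced
    syncope protocol for a heart with severe aortic valve stenosis and
    depressed contractility, per-limb feedback switches and clamp overrides
    for vasodepressor/cardioinhibitory syncope variants, per-beat hemodynamic
    summaries (stroke volume, ejection fraction, transvalvular gradient) and
    pressure-volume loop analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
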