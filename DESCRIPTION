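Package: ulcersim
Title: Hybrid Circuit-ODE/Agent-Based Simulation of Pressure Ulcer Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ischemia-induced reactive hyperemia of skin blood flow
    with a two-capacitor vascular circuit model, calibrates the circuit to
    laser-Doppler flux traces by bounded multistart Nelder-Mead minimization,
    and embeds the calibrated circuit in a stochastic grid agent-based model
    of epithelial damage, inflammation and healing under cyclic external
    pressure. Provides a synthetic trace generator with known ground truth,
    minimal damaging pressure-interval sweeps, and group comparisons between
    control and spinal-cord-injured vascular parameterizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
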