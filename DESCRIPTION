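Package: mabrtemp
Title: Temperature Dependence of Nitrification in Membrane-Aerated
    Biofilm Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic analysis of how temperature shapes nitrification in
    counter-diffusional membrane-aerated biofilms.  Implements a
    one-dimensional two-guild (ammonia oxidiser / nitrite oxidiser) biofilm
    model with a membrane-side oxygen source, a liquid boundary layer at the
    bulk interface, temperature-corrected kinetics and transport, and a
    constant-thickness detachment closure; a scenario engine for simulation
    matrices, temperature-sensitivity statistics and local diffusivity
    sensitivity analysis; batch drawdown rate estimation with windowed
    linear fits and Arrhenius-type temperature-coefficient fitting; and a
    seeded synthetic batch-campaign generator for parameter-recovery
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
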