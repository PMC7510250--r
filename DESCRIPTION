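Package: venapump
Title: Reduced-Order Simulation of the Calf Muscle Venous Pump
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reduced-order (transmission-line) unsteady hemodynamic
    simulator of the lower-limb circulation: a single artery, a porous
    capillary-bed resistance and a single deep vein with a prescribed-motion
    calf segment guarded by two ball check valves. The package sizes the
    idealized circuit from physiological velocity and pressure tables,
    advances the coupled circuit-valve system with a semi-implicit network
    scheme, and computes per-cycle flow volumes, reflux and the calf
    ejection fraction for resting (lying, standing) and walking scenarios
    with healthy, severely incompetent or partially incompetent venous
    valves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tools,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
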