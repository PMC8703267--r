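Package: spinfreeze
Title: Mechanistic Cooling and Freezing Model for Spin-Frozen Pharmaceutical Vials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discrete-time mechanistic simulation of the spin freezing step of
    continuous freeze-drying, in which a rapidly rotating glass vial holding a
    thin annulus of aqueous product is cooled by a jet of cold gas. The package
    models the four phases of spin freezing (liquid cooling, ice nucleation,
    crystal growth, solid cooling) from an energy balance built on Newton's law
    of cooling and cylindrical-shell conduction, calibrates the affine map from
    gas flow rate to the convective heat transfer coefficient from constant-flow
    experiments, propagates input uncertainty to 95% prediction intervals via
    Sobol sampling, apportions prediction variance with Saltelli/Jansen
    total-order sensitivity indices, and inverts the model to compute the
    open-loop gas flow schedule that imposes a target vial temperature profile.
    Includes a synthetic fixture generator emulating constant-flow and
    imposed-profile runs, delimited-text trace I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
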