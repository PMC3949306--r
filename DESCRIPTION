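Package: b55kin
Title: Tight-Binding Kinetics of PP2A-B55 Inhibition by Phosphorylated
    Endosulfine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic models and inference procedures for the regulation of
    the phosphatase PP2A-B55 by Greatwall-phosphorylated Endosulfine
    (pEndos), a molecule that is simultaneously a tight-binding inhibitor
    and a slow substrate of the enzyme ("inhibition by unfair
    competition"). Provides closed-form tight-binding (Morrison) algebra,
    total quasi-steady-state (tQSSA) and explicit mass-action ODE models,
    nonlinear regression with equal-fractional-error weighting for
    initial-velocity and okadaic-acid competition assays, the
    time-dependent automatic-reset model of phosphatase reactivation,
    dose-response IC50 fitting with tight-binding IC50-to-Kd conversion,
    M-phase-exit desequestration simulations, and seeded synthetic-data
    generators emulating the underlying assay designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
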