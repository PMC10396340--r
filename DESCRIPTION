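Package: shedflux
Title: Chemical Uptake at a Contracting Surface via Boundary-Layer Shedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled physical-stochastic model of chemical transport to the
    surface of a small contracting organism such as the freshwater polyp Hydra.
    Provides closed-form solutions of unsteady diffusion to an absorbing (or
    emitting) sphere, uptake integrals between boundary-layer-shedding resets,
    Poisson contraction-event processes with analytic moments of incremental
    and cumulative uptake, Monte-Carlo rate sweeps with contraction budgets,
    contraction-event detection and rate estimation from head/foot tracking
    data, Reynolds/Peclet number calculators, fluid-boundary-layer thickness
    extraction from velocity profiles, and synthetic-data generators that
    emulate video-tracking recordings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
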