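Package: c4dyn
Title: Dynamic Simulation of NADP-ME C4 Photosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic model of NADP-ME C4 leaf photosynthesis for maize,
    sorghum and sugarcane. Couples a reduced-order two-cell-type metabolic
    reaction network (mesophyll and bundle sheath, solved as a stiff ODE
    system) to post-translational enzyme regulation (PPDK regulatory
    protein, Rubisco activase, generic light activation), enzyme
    temperature responses, Ball-Berry stomatal conductance with first-order
    dynamics, and a leaf energy balance. Includes the full gas-exchange
    parameter-estimation workflow (A-Ci curve fitting, Ball-Berry
    regression, stomatal kinetics, Rubisco activation time constant from
    semilog induction slopes, PPDK regulatory protein content by least
    squares, dark respiration), a synthetic gas-exchange data generator
    emulating LI-6800 exports, scenario and sensitivity analyses, flux
    control coefficients and bundle-sheath leakiness diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
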