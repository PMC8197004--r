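Package: remoxsim
Title: Reaction-Transport Simulation of Anodic Oxidation in Reactive
    Electrochemical Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-dimensional, time-dependent simulator of the anodic oxidation
    of paracetamol inside a flow-through porous anode (reactive electrochemical
    membrane). Couples hydroxyl-radical reaction kinetics, Butler-Volmer
    electrode kinetics with a dual-phase (solution/matrix) secondary current
    distribution, advection-diffusion-reaction transport of four dissolved
    species, Darcy flow with electroosmotic augmentation and gas-bubble pore
    blockage, and the relaxation dynamics of the oxygen gas volume fraction.
    Provides post-processing of permeate flux, degradation-depth profiles and
    electrode potential drop, an independent well-mixed verification oracle,
    conservation audits, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
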