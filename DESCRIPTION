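Package: oscdesign
Title: Promoter Architecture and the Dynamics of Two-Gene Genetic Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic analysis of two-gene
    activator-inhibitor genetic oscillators that differ in how the
    repressor acts at the activator promoter: competitive DNA binding,
    non-competitive (independent-site) binding, or post-translational
    inhibition.  Provides the nondimensional ODE models and their
    Jacobians and nullclines, fixed-point location and eigenvalue
    classification, bifurcation scans with Hopf/SNIC event detection,
    two-dimensional period maps over transcription-strength parameter
    space, and exact Gillespie simulation of the corresponding
    birth-death reaction networks for noise-induced oscillation
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
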