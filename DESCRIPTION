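Package: impulseSIS
Title: State-Dependent Impulsive SIS Models with Saturated Treatment and
    Threshold Pulse Vaccination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and bifurcation analysis of an SIS epidemic model
    with saturated treatment under a susceptible-threshold pulse
    vaccination policy: once the susceptible population reaches a
    threshold S_T, a fraction q is vaccinated instantaneously.  Provides
    equilibrium and local-stability classification of the planar ODE
    core (including its backward bifurcation), event-driven hybrid
    simulation of the impulsive system, the closed-form disease-free
    (semi-trivial) periodic solution with its Floquet multiplier, a
    numerical Poincare map on the post-vaccination section with
    fixed-point (order-1 periodic solution) detection, and computation
    of the critical parameter values in the vaccination fraction q, the
    threshold S_T and the recruitment rate A where the semi-trivial
    solution exchanges stability, with transcritical-versus-pitchfork
    classification from the map derivatives.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
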