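Package: biosensim
Title: Axisymmetric Finite-Element Simulation of Amperometric Biosensors
    with Perforated Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transient simulation of multilayer amperometric enzyme
    electrodes covered by a perforated outer membrane. Solves the coupled
    nonlinear Michaelis-Menten reaction-diffusion equations for substrate
    and product on a 2-D axisymmetric unit cell (selective membrane,
    enzyme layer, perforated membrane with seven hole geometries, external
    diffusion layer) with a Galerkin finite-element method on quadratic
    triangles, implicit time stepping and Newton-Raphson iteration.
    Computes the transient electrode current, the steady-state current and
    the half-time response as functions of the membrane perforation level
    and the enzyme filling level, and ships independent one-dimensional
    finite-difference and closed-form linear-kinetics reference solvers
    used as correctness oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
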