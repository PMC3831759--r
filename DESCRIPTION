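Package: cervodil
Title: Poroelastic Finite-Element Simulation of Cervical Dilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dynamic Biot poroelastic finite-element model of cervical
    tissue with coupled solid displacement, pore pressure and Darcy
    velocity fields, integrated in time with an implicit Newmark scheme.
    Builds structured annulus and consolidation-column meshes, simulates
    mechanical (Hegar-style) versus hydraulic balloon (CCBD-style)
    cervical dilation protocols, calibrates tissue stiffness and
    permeability from pressure-opening data by least squares, and ships
    closed-form Terzaghi, Lame and single-degree-of-freedom oracles for
    verification. Results export to legacy VTK, CSV and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
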