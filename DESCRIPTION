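Package: phagospread
Title: Moving-Boundary Simulation of Phagocytic Cell Spreading
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Axisymmetric moving-boundary simulation of immune-cell spreading
    during frustrated phagocytosis.  The cell is modelled as a highly viscous
    fluid droplet bounded by a cortex under biphasic tension, driven by
    short-range substrate adhesion (Brownian zipper), an active protrusion
    stress (protrusive zipper), or protrusion combined with discrete
    receptor-ligand adhesion sites.  The creeping-flow field is solved with a
    penalty-stabilised quadrilateral finite element method and an Uzawa-style
    velocity-pressure iteration; the contact line advances irreversibly as
    membrane reaches the substrate.  Includes constitutive laws for cortical
    tension, protrusion stress and membrane-fluctuation capture distance,
    Young-Dupre equilibrium analysis, and post-processing of contact-area
    kinetics (sigmoid spreading speed, early-phase power-law exponent).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
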