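Package: aqueduct
Title: Pressure Transmission Through the Vestibular Aqueduct to the Round
    Window Membrane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale fluid-structure model of cerebrospinal-fluid pressure
    transmission through the vestibular aqueduct (VA) into the inner ear and
    onto the round window membrane. Provides parametric inner-ear geometry for
    a grid of normal and enlarged (LVAS) aqueducts, synthetic labelled voxel
    phantoms with centerline-based VA width morphometry and Cincinnati-criteria
    classification, iso-surface extraction with STL/VTK export, a clamped
    Kirchhoff plate solver for the membrane with closed-form oracles and a mesh
    convergence harness, a reduced laminar duct + closed cavity + compliant
    membrane transient solver (resistance-inertance-compliance network driven
    by half-sine pressure pulses), and an experiment harness that sweeps load
    and aqueduct width and reports peak deflection, peak stress, response lag
    and pressure-limiting behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    pracma,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
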