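Package: spinebrace
Title: Reduced-Order Musculoskeletal Simulation of Brace Correction in
    Adolescent Idiopathic Scoliosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale musculoskeletal statics of a scoliotic thoracolumbar
    spine (Rigo A3 double thoracic plus lumbar pattern) under gravity, optimized
    trunk muscle forces, and Cheneau-style brace pressure patches. Provides a
    parametric scoliotic spine generator with literature-based tissue
    properties, per-level gravity loads, pressure-patch load cases for a
    corrective-pressure sweep, a rigid-vertebra / elastic-joint equilibrium
    solver with tension-only ligaments and static muscle-force optimization,
    radiographic measurement (Cobb angles, kyphosis, lordosis, apical vertebral
    translation, correction rates), and intervertebral disc height, von Mises
    stress, and muscle axial-force concave/convex ratio metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
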