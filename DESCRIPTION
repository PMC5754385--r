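Package: endorod
Title: Cosserat-Rod Physics for Endovascular Instrument Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless physics engine for simulating catheters and
    guidewires as discrete Cosserat rods: quaternion material frames with
    bend/twist elasticity, inextensibility enforced by a tridiagonal chain
    of distance constraints inside a block-iterative Projected Gauss-Seidel
    solver, concentric guidewire-in-catheter coupling, AABB-tree mesh
    collision with Coulomb friction, RMS-distance instrument calibration
    against reference centrelines, and supporting angioplasty models
    (contrast propagation, balloon inflation with vessel morphing, stent
    deployment, keyframe cardiac motion). Ships synthetic vascular phantom
    generators, a rod-compression benchmark harness, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
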