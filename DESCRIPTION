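Package: bimodbeam
Title: Bimodular Functionally Graded Beam Analysis of Cortical Bone Under
    Bending Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of cortical-bone beams under four-point-bending fatigue
    with a bimodular (different tension/compression) functionally graded
    elastic model. Recovers the logarithmic modulus-gradient parameters and
    the neutral-axis position from surface strain pairs measured over fatigue
    life, via closed-form section integrals and a nested one-dimensional
    root-finding inverse solver; includes segmented (breakpoint) regression of
    strain trajectories, a synthetic strain-trajectory generator, and an
    independent plane-stress finite-element verification of the analytical
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
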