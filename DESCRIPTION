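Package: rotaryF1
Title: Rotational Biasing, Conformational Landscapes and Energetics for
    F1-Type Rotary Motors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing rotary molecular motors of the F1-ATPase
    family. Implements a mean-rotation-angle collective variable with a
    moving harmonic bias and nonequilibrium work/torque accounting (the
    "flexible rotor" scheme, in which only the average rotation angle of a
    group is restrained), a Calpha covariance PCA landscape for
    alpha/beta-pair conformations, a stator-frame gamma rotary-angle
    algorithm, per-frame trajectory metrics (helicity, contacts, helix
    bending, chi1 rotamer states, minimum distances), a torque to
    proton-motive-force energetic bookkeeping, and a seeded coarse-grained
    toy rotary-motor simulator that generates the synthetic structures and
    trajectories used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
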