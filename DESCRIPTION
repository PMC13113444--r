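Package: gaitmuscle
Title: Non-Invasive Muscle Force Estimation from Slow-Gait Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates normalized active and passive lower-limb muscle force
    profiles over the gait cycle from kinematics alone, without
    electromyography. A generic musculoskeletal geometry is scaled to a
    subject's anthropometry (linear regression for missing trunk dimensions,
    per-segment geometric scale factors, proportional segment masses), muscle
    origin and insertion points are mapped between anatomical and kinematic
    segment frames with homogeneous transition matrices, and time-varying
    muscle-tendon lengths drive a simplified Hill-type force-length model
    parameterized by a muscle architecture index regressed from pennation
    angle and optimal fiber length. Includes cycle-offset compensation of
    active-force waveforms, Pearson and Spearman waveform validation tools,
    a TRC marker-trajectory reader and writer, and a deterministic synthetic
    slow-gait trial generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
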