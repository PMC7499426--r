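Package: larvakin
Title: Kinematic Phenotyping of Larval Zebrafish Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, tracking and statistical analysis of larval zebrafish
    swimming behavior. Generates synthetic cohorts with clutch structure and
    genotype effects, simulates beat-and-glide slow-swim sessions and
    acousto-vestibular escape trials with full ground truth, renders and tracks
    larva silhouettes, segments swim bouts from tail-angle traces, computes
    per-bout kinematics (distance, duration, speed, oscillations, tail beat
    frequency, bend amplitudes), classifies forward swims versus routine turns,
    selects escape responses, aggregates per-fish summaries, and compares
    genotypes with linear mixed models (random clutch intercept), Type II Wald
    chi-square tests and an eigenvalue-based effective-number-of-tests
    correction of p-values.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    e1071,
    signal,
    yaml,
    jsonlite,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
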