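Package: esndisc
Title: Discrimination-Based Training of Echo State Networks for Motor
    Pattern Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains echo state networks to map multi-channel temporal
    inputs onto two-dimensional motor trajectories using a three-step,
    cerebellum-inspired algorithm: separation-based training of the
    input weights that pushes per-class attractor dynamics apart,
    approximation-based ("innate") training of the recurrent weights by
    recursive least squares (FORCE), and linear readout training that
    draws the output trajectory during a motor phase.  Includes the
    separation and approximation diagnostics used to steer training
    (pairwise separation, linear-separation rank, between- and
    within-class scatter traces, discriminant ratio, kernel-quality D),
    a synthetic generator of class-structured multi-channel patterns
    with jitter, trajectory targets and evaluation utilities
    (trajectory error, rasterization, nearest-template classification,
    scaling-factor sweeps), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
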