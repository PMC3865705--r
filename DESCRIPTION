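Package: opmplace
Title: Place-Cell Spatial Coding Analysis for the Object Place Memory Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for hippocampal place-cell recordings made
    during the object place memory (OPM) task: familiarization (T1), sample
    with two objects (T2), and choice with one object moved (T3). Builds
    occupancy-normalized firing rate maps on a fixed 2-cm grid with
    low-occupancy masking and valid-support Gaussian smoothing; computes
    Skaggs spatial information, place fields by contiguous-pixel detection,
    rate-weighted centers of mass, between-trial COM shifts, similarity
    scores, and object-vector indices; classifies units as stable, unstable,
    emerging, vanishing, or inactive across trial transitions; scores object
    exploration (visits, exploration ratio, OPM discrimination ratio, percent
    time moving); and applies a Shapiro-Wilk-gated comparison scheme
    (t-test vs. Kolmogorov-Smirnov / Mann-Whitney, chi-square on class
    frequencies). A synthetic-session generator produces arenas, confined
    random-walk trajectories, Gaussian-tuned units with inhomogeneous-Poisson
    spiking, and known across-trial dynamics, including an NMDAR-antagonist
    (CPP)-like perturbation, so every stage is testable with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
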