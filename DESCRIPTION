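Package: lickbox
Title: Directional-Licking Operant Task Simulation and Lickometer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free computational core of a strain-gauge lickometer and
    directional-licking operant conditioning platform. Provides offline and
    online (comparator-emulating) lick detection from strain-gauge force
    traces with validation against ground truth (one-to-one matching,
    sensitivity, positive predictive value, threshold sweeps); a
    discrete-event finite-state machine for the two-spout discriminative and
    serial reversal-learning task driven by pluggable agent policies;
    session performance analysis (moving-average block performance,
    trials-to-criterion, reversal summaries); event-triggered MAD-normalized
    averaging of denoised calcium traces with 3x-MAD modulation calling and
    initiation/licking/postlick classification, plus frame-loss
    quantification; and a simulation of the magnet-and-three-Hall-sensor
    ring commutator with its sector-decoding logic. A synthetic-data module
    generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
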