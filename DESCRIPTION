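Package: oscseq
Title: Oscillator-Ensemble Simulation of Rhythmic Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates sequence learning by ensembles of phase oscillators
    that attune, through phase resets and frequency retuning, to the
    polyphony of rhythms generated when a stimulus sequence is repeated.
    Each oscillator is a discrete-time phase-locked loop that locks to the
    recurrence rhythm of one input symbol; a reset-weighted error signal
    classifies test items as congruent or incongruent continuations of the
    learned sequence. Includes generators for binary Gabor-patch sequences
    and audiovisual (crossmodal) sequences, Monte-Carlo experiment drivers
    for accuracy curves, phase-frequency histogram and cluster analyses,
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
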