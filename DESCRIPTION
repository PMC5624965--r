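Package: woodknock
Title: Impact-Oscillator Drumming and Flap-Rate Models for Large Woodpeckers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models two periodic-and-transient motions of large woodpeckers.
    Drumming and Campephilus double knocks are simulated as a damped harmonic
    oscillator whose bill impacts a rigid wall with a coefficient of
    restitution, driven by periodic or impulsive forcing; impact trains are
    reduced to cadence statistics and classified as periodic drumming or a
    transient double knock. Cruising flap rates are predicted from a
    Strouhal-number vortex-shedding model and converted between raw
    (wall-clock) and intrinsic rates via the flapping duty fraction, with
    frame-count arithmetic for video-derived rates. Seeded synthetic-data
    generators emit knock trains, rendered knock audio, and frame-indexed flap
    sequences with known ground truth so every analysis stage is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
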