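Package: trfaad
Title: Temporal Response Functions and EEG-Based Auditory Attention Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cortical tracking of speech in two-talker
    ("cocktail party") listening with electroencephalography (EEG).
    Implements relative-RMS segmentation of speech into high-RMS-level
    (intelligibility-critical) regions, Hilbert temporal-envelope extraction
    with band-pass filtering, deterministic EEG conditioning (mastoid
    re-referencing, zero-phase Butterworth and FIR filtering, epoching,
    downsampling), forward and backward temporal-response-function (TRF)
    models estimated by ridge regression with leave-one-out cross-validation,
    correlation-based attended-speaker classification across
    signal-to-noise-ratio conditions and decoding-window durations, and a
    seeded synthetic cocktail-party generator with known ground truth for
    end-to-end validation by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
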