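Package: trfnirs
Title: Time-Resolved fNIRS Motor-Imagery Decoding and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved functional near-infrared spectroscopy
    (TR-fNIRS) brain-computer-interface analysis. Implements the full chain
    from raw distributions of photon times-of-flight (DTOFs) to yes/no
    motor-imagery decoding: DTOF truncation and mean time-of-flight
    extraction, motion-artifact correction, cosine-basis detrending and
    hemodynamic smoothing, conversion of mean time-of-flight changes to
    brain absorption changes via Monte-Carlo-derived sensitivity factors,
    two-wavelength inversion to oxy- and deoxyhemoglobin concentrations,
    block-averaged epoch features, and LDA/SVM leave-one-out classification
    with exhaustive feature-subset search. A layered Monte-Carlo photon
    transport model with per-layer time-resolved partial pathlengths and a
    physics-based synthetic cohort generator make the whole pipeline
    testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
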