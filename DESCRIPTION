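Package: piezobp
Title: Beat-to-Beat Blood Pressure Tracking from Piezoelectric Pulse Waves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for cuff-anchored beat-to-beat
    blood pressure measurement from radial-artery pressure pulse waves (PPW)
    recorded with a piezoelectric sensor. Generates synthetic arterial
    pressure waveforms with known per-beat systolic and diastolic values,
    models the linear pressure-to-voltage transduction of a PVDF pulse
    sensor and the analog front end (AC coupling, instrumentation-amplifier
    gain, Butterworth band limiting), performs baseline-wander removal and
    wavelet denoising, detects per-beat peak and valley feature points by
    adaptive thresholding, converts inter-beat voltage changes to pressure
    changes via the sensor sensitivity and circuit gain, accumulates them
    onto an initial cuff reading, and evaluates tracking accuracy against
    reference readings with mean-absolute-error and standard-deviation
    statistics of the kind used in device validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
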