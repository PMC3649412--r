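Package: semgfis
Title: Neuro-Fuzzy Characterization of Arm Movements from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end myoelectric movement characterization: preprocesses
    multi-channel surface electromyography (sEMG) recordings (calibration, DC
    removal, 20-450 Hz band-pass, 60 Hz notch, cue-aligned windowing) into
    per-channel RMS feature vectors, seeds a Sugeno fuzzy inference system by
    subtractive clustering, trains it with hybrid ANFIS learning (least-squares
    consequents, gradient-descent premises), and decodes the continuous network
    output into one of seven arm/hand movement classes. Includes a synthetic
    sEMG session generator emulating the cued acquisition protocol so the whole
    pipeline can be exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
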