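Package: intentnet
Title: Multilayer Motor-Intent Analysis of Kinematics and Cardiac Biorhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Differentiates levels of motor intent (deliberate forward reaches
    versus spontaneous backward retractions; performing versus non-performing
    body side) from multi-sensor upper-body kinematics and single-lead ECG.
    Implements micro-movement spike (MMS) standardization of angular
    acceleration waveforms, Gamma maximum-likelihood noise-to-signal ratios,
    earth mover's distance between MMS amplitude histograms, cross-correlation
    network connectivity with weighted clustering coefficients, and heart-body
    lead/lag estimation.  A synthetic session generator emulates the pointing
    task (motion capture at 240 Hz, ECG at 256 Hz) so the full pipeline is
    testable without access to human recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    boot,
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
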