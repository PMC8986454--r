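Package: scgcti
Title: Seismocardiogram Fiducial Points and Cardiac Time Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and evaluation pipeline for dual-channel ECG and
    seismocardiogram (SCG) recordings: zero-phase Butterworth band-pass
    filtering, R/Q-wave detection, beat-quality screening, R-synchronized
    ensemble averaging, detection of the four valvular fiducial points
    (mitral closure/opening, aortic opening/closure) on the averaged beat,
    classification of waveforms as traditional or non-traditional, and
    derivation of cardiac time intervals (PEP, IVCT, LVET, IVRT).  Includes
    RR-interval sequence alignment for synchronizing M-mode sonogram
    annotations to the device timeline, a method-agreement layer
    (reference ranges, Welch, F and G tests) against a healthy-subject
    benchmark, and a synthetic ECG+SCG cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
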