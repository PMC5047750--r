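Package: stressgate
Title: Single-Cell Logic-Gate Analysis of Dual Stress Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses single-cell time traces of the yeast
    general stress response factors Msn2 and Msn4 driving fast- and
    slow-kinetics target promoters. Provides a kinetic generator of
    transcription-factor nuclear translocation and promoter activation
    (switch/rheostat/shared-site competition scheme), per-cell trace
    feature extraction (peaks, AUC, half-max translocation times,
    endpoint expression), TF-level binning with responder statistics,
    and inference of AND/OR gate logic and switch-versus-rheostat
    regulator modes, together with a reproducible simulate-to-report
    pipeline over plain-text files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
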