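Package: emgdi
Title: ECG Artifact Cancellation and Breath-Wise Diaphragm EMG Amplitude
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel esophageal diaphragm
    electromyography (EMGdi) recorded together with a separate ECG
    reference channel and a respiratory flow signal.  Implements
    reference-channel least-mean-squares (LMS) adaptive FIR filtering to
    remove the ECG artifact from every EMGdi channel, breath segmentation
    from zero-flow points, per-breath mean RMS amplitude and
    EMGdi/EMGdiMax normalisation, an emulation of the classical manual
    between-QRS interval selection method (including two documented rater
    strategies), method-agreement statistics (intraclass correlation,
    Bland-Altman limits of agreement, repeated-measures interaction), and
    a ground-truth synthetic recording generator for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
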