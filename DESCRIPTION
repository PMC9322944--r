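Package: stroopfc
Title: Prefrontal fNIRS Connectivity Features and Four-Class
    Neuropsychiatric State Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing and classification pipeline for prefrontal
    functional near-infrared spectroscopy (fNIRS) recordings acquired
    during a colour-word Stroop task. Converts dual-wavelength raw light
    intensities to oxy-/deoxy-haemoglobin concentration changes via the
    modified Beer-Lambert law, screens channels by coefficient of
    variability, applies zero-phase high-pass filtering, and builds
    partial-correlation functional connectivity matrices corrected for
    the global systemic signal. Connectivity matrices are split into
    cognitive-mode and default-mode components by eigendecomposition,
    summarised as weighted-graph global efficiency, and combined with a
    behavioural cognitive quotient to train naive Bayes, linear
    discriminant, and Pearson-VII-kernel support vector classifiers
    under repeated stratified cross-validation. A seeded synthetic
    cohort generator emulating the task protocol makes the full chain
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    e1071,
    kernlab,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
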