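Package: lsdlspectra
Title: Amplitude-Band Decomposition and Classifier Benchmarking for FTIR Biofluid Spectra
Version: 0.1.0
Authors@R:
    person("lsdlspectra", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for urine FTIR (Fourier-transform infrared) spectral
    classification pipelines: a linear series decomposition learner (LSDL)
    that learns an amplitude-threshold band maximizing a normalized
    Euclidean-distance class-separability index, a 12-feature spectral
    signal battery (time-domain, autoregressive, entropy and fractal
    features), SMOTE class balancing, stratified cross-validated
    benchmarking of nine classifiers with accuracy, sensitivity,
    specificity and AUC tables, a PCA separability projection, and a
    seeded synthetic cohort generator that emulates a prostate-cancer
    urine-EV FTIR study design (31 noncancer / 22 cancer subjects,
    replicate averaging versus single acquisition, Gleason-grade
    subgroups).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    FNN,
    quadprog,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
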