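Package: stressconn
Title: Cortical Functional Connectivity and Stress-Induced Cardiac Susceptibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline linking pre-stress cortical local field potential
    (LFP) functional connectivity to stress-induced cardiac dysfunction in
    individual rats. Provides ECG R-peak detection, arrhythmia (skipped-beat)
    scoring and heart-rate-variability based susceptibility classification,
    EMG root-mean-square sleep scoring, windowed FFT band-power spectrograms,
    pairwise band-power envelope correlation with group-level
    Kolmogorov-Smirnov and per-frequency t statistics, and PCA plus linear-SVM
    leave-one-out prediction of susceptibility. A synthetic multichannel
    biosignal generator with known ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
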