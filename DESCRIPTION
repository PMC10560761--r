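Package: wmdan
Title: Working-Memory EEG Analysis with a Dense Attention Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a lateralized visual
    change-detection working-memory EEG study comparing a patient and a
    control group. Generates synthetic epoched EEG cohorts with planted
    group-level alpha-suppression effects, a lateralized sustained
    potential (contralateral delay activity) and 1/f background noise;
    computes behavioral capacity (Pashler K) and reaction-time
    variability; extracts the contralateral delay activity; performs
    Morlet-wavelet time-frequency decomposition with decibel baseline
    normalization and phase-by-band region-of-interest statistics;
    reduces epoched data to per-subject time-course feature vectors by
    incremental stepwise averaging; classifies subjects with a dense
    attention network under repeated leave-one-out cross-validation
    alongside a bank of reference classifiers; and projects the
    network's attention distribution onto the task timeline and
    thresholded group-difference time-frequency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, car, jsonlite, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), e1071, class, glmnet, randomForest, withr, knitr, rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
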