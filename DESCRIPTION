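Package: reverbdecode
Title: Time-Resolved MEG Decoding of Sound Sources and Reverberant Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-resolved multivariate
    decoding of auditory magnetoencephalography (MEG) responses in a 3x3
    factorial design of impact sound sources rendered in reverberant spaces
    of increasing size. Provides a synthetic-data generator that emulates the
    factorial epoch structure (transient source-discriminative and sustained
    space-discriminative sensor patterns, spatially correlated noise,
    room-impulse-response stimulus synthesis, gamma-distributed behavioral
    reaction times); epoched-data preprocessing (baseline correction, 30-Hz
    zero-phase low-pass); pairwise linear-SVM decoding with trial
    subaveraging and leave-one-out cross-validation, including pooled,
    cross-classified, sensorwise and temporally generalized variants;
    sign-permutation cluster inference with bootstrap latency confidence
    intervals and FDR maps; gammatone-cochleogram stimulus dissimilarity
    controls; and ordinal-versus-categorical space-model comparison by
    representational similarity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    signal,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
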