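Package: phonupdrs
Title: Estimating Parkinson's Disease Symptom Severity from Telephone-Quality Sustained Phonations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating Unified Parkinson's Disease
    Rating Scale (UPDRS) scores from sustained vowel phonations transmitted
    through a simulated noisy cellular voice channel. Provides a synthetic
    cohort generator with severity-linked voice degradation, a
    transmitter/channel/receiver simulation (pre-coding noise, frame-based
    LPC speech codec, intersymbol-interference channel with MMSE
    equalization), extraction of 132 dysphonia measures (jitter, shimmer,
    HNR, glottal quotient, RPDE, DFA, PPE, GNE, VFER, EMD excitation
    ratios, MFCCs and F0 summaries), feature-selection voting over four
    selectors with the one-standard-error rule, and random-forest mapping
    to UPDRS validated by repeated 10-fold cross-validation and a
    subject-calibrated tracking scheme with mean-absolute-error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
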