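Package: shockable
Title: Shockable Rhythm Detection from Short ECG Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating shock-advise algorithms for
    automated external defibrillators. Implements an ECG preprocessing chain
    (1-30 Hz monitor bandwidth at 250 Hz), AHA-style segment labelling with
    fine-VF, asystole and slow-VT exclusion rules, a library of 30 established
    ventricular-fibrillation detection features (temporal, spectral,
    time-frequency and complexity measures), harnesses for five classifier
    families with patient-grouped model selection, patient-wise bootstrap
    performance estimation (sensitivity, specificity, balanced error rate),
    bootstrap-embedded recursive feature elimination with the
    one-standard-error subset rule, and a synthetic ECG corpus generator that
    emulates Holter-like and out-of-hospital cardiac-arrest-like rhythm
    populations so the full study protocol runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    glmnet,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
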