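Package: localglobal
Title: Simulation and Single-Trial EEG Decoding of the Local-Global Auditory Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pre-registered analysis of auditory regularity
    encoding in comatose patients with the local-global oddball paradigm:
    stimulus-schedule generation with global and local deviance labels,
    synthetic multichannel EEG epochs with plantable effect topographies,
    preprocessing (zero-phase band-pass, epoching, artifact rejection,
    global-field-power normalization), single-trial topographic decoding via
    per-condition Gaussian mixture models, support-vector-machine decoding of
    concatenated and time-resolved features, permutation-based significance of
    test-set AUC, and cohort-level statistics (binomial power simulation,
    Fisher/Pearson/Kruskal-Wallis outcome tests, forward model selection over
    sedative covariates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
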