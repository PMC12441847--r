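Package: nanodst
Title: Nanomotion-Based Drug Susceptibility Testing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for label-free, nanomotion-based drug
    susceptibility testing of cancer cells. Cantilever-deflection time
    series are summarized by quantile spectrograms (per-frequency
    quantiles of Welch segment periodograms over successive time
    windows), reduced to scalar band descriptors (band power, spikiness,
    Jensen-Shannon distance to the chi-squared periodogram law), and
    classified with forward-selected two-feature logistic models under a
    stratified 4:1:1 train/validation/test protocol. Includes a seeded
    synthetic nanomotion-signal generator, resazurin relative-viability
    computation and variable-slope (four-parameter logistic) IC50
    fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
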