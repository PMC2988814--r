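Package: echofish
Title: Species Classification of Fish Echoes from Simulated Biosonar Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how echolocating odontocetes could recognize
    fish species from single sonar echoes. Synthesizes dolphin-like and
    porpoise-like emission clicks, simulates aspect-angle-dependent fish echoes
    from species-specific internal-reflector models, extracts Hilbert-envelope
    statistics for quadratic discriminant classification, builds band-limited
    dB-scaled spectrograms for linear maximum-margin classification, and
    interprets and validates the learned decision weights ("decision echoes")
    by smoothing, noise injection, and principal-component ("eigen-fish")
    resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
biocViews: Classification, SupportVectorMachine, DimensionReduction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
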