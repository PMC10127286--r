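Package: misogate
Title: Predicting Multi-Input Transcriptional Logic Gates from Single-Input Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and predicting compressed Boolean logic gates
    (AND, NOR, A NIMPLY B, B NIMPLY A) built from engineered LacI-family
    repressors and antirepressors. Processes plate-reader OD600/GFP data into
    unit-scaled fluorescence, extracts coarse-grained single-input gate
    parameters (leakiness epsilon and dynamic increment sigma) with statistical
    phenotype classification, enumerates the combinatorial design space of
    regulatory core domains, DNA recognition functions and operator positions,
    screens transcription-factor pairs for compatibility, parameterizes
    quadratic corner-state models of two-input gates, and validates predictions
    against measurements with ANOVA/Tukey-Kramer logic tests and fold-error
    metrology. Includes a synthetic plate-data generator so the whole pipeline
    is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
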