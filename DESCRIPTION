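Package: diffrhythm
Title: Differential Circadian Rhythmicity Analysis for Two-Group
    Expression Timecourses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cosinor rhythmometry for two-group gene-expression
    timecourses: single-group cosinor fitting with a fixed 24-h period,
    nested offset-model inference for group differences in mesor,
    amplitude and acrophase with 95% confidence-interval decision rules,
    BIC-weight model selection that categorizes transcripts as
    arrhythmic, loss, gain, change or same, 2^-ddCt relative
    quantification of qPCR data with a phase-specific baseline
    convention, report-level percent-change summaries, and a synthetic
    timecourse generator emulating a two-diet mouse liver study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
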