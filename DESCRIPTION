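Package: chromqbd
Title: Quality-by-Design UHPLC Method Development with Linear Solvent
    Strength Retention Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Computer-assisted reversed-phase gradient method development
    in the Quality-by-Design framework. Fits per-compound linear solvent
    strength (LSS) retention models from a 12-run gradient time x
    temperature x pH calibration design, predicts gradient chromatograms
    with Gaussian peak widths, maps the design space where the critical
    resolution meets an acceptance criterion, selects a robust working
    point, runs full-factorial virtual robustness studies (3^6 = 729
    in-silico experiments over six method parameters), and computes UV
    response-corrected area-percent purity. Ships a synthetic
    nine-compound apixaban-like reaction mixture generator so the whole
    pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'core-model.R'
    'calibration.R'
    'design-space.R'
    'robustness.R'
    'quantitation.R'
    'synthetic-data.R'
    'io.R'
    'cli.R'
    'show-methods.R'
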