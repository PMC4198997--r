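Package: aqeval
Title: Entropy-Weighted Air Quality Evaluation Against Regulatory Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comprehensive ambient air quality evaluation combining
    information-entropy indicator weighting with nearest-neighbour
    classification against the threshold vectors of regulatory standards.
    Ships the Chinese ambient air quality standards GB 3095-1996 (three
    levels) and GB 3095-2012 (two levels) as built-in threshold tables, a
    bundled Beijing February 2014 daily pollutant dataset, calibration
    routines that pin the entropy constant and the classification
    configuration against published reference results, and a synthetic
    generator for haze-episode pollutant series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
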