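Package: alcosense
Title: Alcohol-Content Estimation from Nanomechanical Sensor-Array Smell Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of electronic-nose measurements made with a
    membrane-type surface stress sensor (MSS) array. Extracts four kinetic
    parameters (initial-rise slope, quasi-equilibrium slope, initial-decay
    slope, maximum height) from adsorption-desorption response cycles, fits
    Gaussian-kernel ridge regression models of alcohol content, tunes the
    ridge strength and kernel width by S-fold cross-validation, performs
    exhaustive bitmask feature-subset search with usage-rate summaries, and
    reports parity, correlation and principal-component summaries. Includes a
    seeded synthetic generator of multi-component first-order sorption
    response traces so the whole pipeline is testable without raw sensor
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), deSolve, withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
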