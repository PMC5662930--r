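Package: rootzones
Title: Developmental Zonation of Root Apices from Cell Length Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segments epidermal cell-length profiles of root apices into
    developmental zones (division, elongation, mature) with heteroscedastic
    piecewise Gaussian linear multiple change-point models: dynamic-programming
    optimal and top-N segmentation, slope-heuristic selection of the number of
    zones, posterior zone-occupancy and change-point distributions with
    uncertainty intervals, a Gaussian change-in-the-variance model for residual
    series, biologically guided choice among well-supported segmentations, and
    cohort-level meta-analysis (zone-length means, correlation structure,
    principal component analysis). Ships reference tables for 36 maize lateral
    roots and a synthetic profile generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
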