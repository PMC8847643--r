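Package: vbarc
Title: Volume-Based Optimal Partial-Arc Angle Planning for VMAT Lung Sparing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for volume-based selection of personalized partial-arc
    gantry angles in volumetric modulated arc therapy (VMAT) of central
    thoracic targets. Converts planning-target-volume and thorax geometry
    (transverse diameter, target width and length, lung volumes) into the
    optimal partial-arc angle that bounds the low-dose lung volume (lung V5),
    sequences that angle into deliverable clockwise/counter-clockwise arc
    sets, and evaluates plans with dose-volume histograms, homogeneity and
    conformity indices, organ-at-risk constraint reports and gamma-index
    comparison. Includes a parameterized digital thorax phantom and a simple
    attenuated parallel-beam arc-dose simulator so the whole chain can be
    exercised and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
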