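Package: larvalheart
Title: Quantification of Heart Regeneration Kinetics in Zebrafish Larvae from
    Fluorescence Time-Lapse Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify cardiac regeneration in genetically ablated
    zebrafish larval ventricles from dual-channel (BFP/mCherry) fluorescence
    time-lapse videos. Provides systole-frame selection and control-calibrated
    threshold segmentation of ventricular fluorescent areas, normalization of
    regeneration kinetics to negative-control larvae, kymograph-based cardiac
    function readouts (heart rate, ejection fraction, beat lengths, corrected
    contraction intervals, chamber diameters), a GraphPad-Prism-style
    statistical workflow (ROUT outlier removal, two-way and one-way ANOVA with
    Tukey-Kramer comparisons, pooled t-tests, residual normality tests), and a
    seeded synthetic beating-heart video generator with ground truth so the
    whole pipeline can be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    nortest,
    car,
    pracma,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
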