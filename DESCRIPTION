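Package: tendonmech
Title: Patellar Tendon Mechanics from Dynamometry and Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for in-vivo patellar tendon mechanical
    properties measured with synchronized dynamometry and B-mode
    ultrasound. Provides a synthetic-data generator with known ground
    truth (ramped isometric force traces, speckle-textured image stacks
    with two displacing landmarks, shear-wave-velocity pixel maps, and
    pre/post training cohorts), a sub-pixel pyramidal Lucas-Kanade
    landmark tracker, force-elongation curve construction with
    quadratic fitting and fit-quality gating, common-force
    standardization and 60-100 percent stiffness slopes, shear-wave
    elastography saturation quality control, test-retest reliability
    statistics (ICC(3,1), typical error, coefficient of variation),
    and mixed-design two- and three-way repeated-measures ANOVA with
    partial eta squared and Bonferroni post hocs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tiff,
    jsonlite,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
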