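Package: kneealign
Title: Automated Knee-Alignment Measurement from Radiograph Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the femoro-tibial angle (FTA) from anatomical landmark
    outlines of standard knee radiographs under nine published axis-definition
    combinations, predicts the mechanical hip-knee-ankle angle (HKAA) by linear
    regression with 5-fold cross-validation, and summarises agreement with the
    full-limb gold standard (Pearson correlation, absolute-agreement intraclass
    correlation with exact F-based confidence intervals, mean absolute error,
    and Bland-Altman statistics). Includes a synthetic lower-limb landmark
    generator with known ground-truth alignment for end-to-end validation of
    the measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
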