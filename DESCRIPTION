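Package: aortaflow
Title: Aortic Regurgitation Quantification from Phase-Contrast CMR Velocity Images
Version: 0.1.0
Authors@R:
    person("Aortaflow", "Developers", email = "aortaflow@example.org", role = c("aut", "cre"))
Description: Quantifies aortic regurgitation from time-resolved phase-contrast
    cardiovascular magnetic resonance (PC-CMR) velocity image series in the
    ascending and descending aorta. Provides velocity decoding, aliasing
    unwrapping, planar eddy-current background-offset correction,
    magnitude-image lumen segmentation with phase-to-phase propagation, and
    ROI flow integration; per-patient regurgitant volume and fraction,
    holodiastolic flow reversal, diastolic flow-reversal velocity and
    severity classification; linear ascending-to-descending threshold
    transfer; and diagnostic-performance evaluation (sensitivity,
    specificity, likelihood ratios, Bland-Altman, ROC/AUC). Includes a
    velocity-encoded phantom and cohort simulator so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
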