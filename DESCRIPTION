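Package: iclvault
Title: Vault Prediction and Size Selection for Implantable Collamer Lenses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sizing support and validation statistics for posterior-chamber
    implantable collamer lens (ICL) surgery. Implements a linear central-vault
    prediction formula over ultrasound-biomicroscopy ciliary-sulcus biometry
    (horizontal and vertical sulcus-to-sulcus diameter, crystalline lens
    thickness), a target-window size-selection rule over the four manufactured
    ICL lengths, postoperative vault classification, Bland-Altman agreement
    analysis between predicted and achieved vault, exact Fisher comparison of
    anatomic UBM features between large-prediction-error groups, and a
    synthetic-cohort generator so the whole pipeline can be exercised and
    calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
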