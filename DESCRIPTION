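Package: ieegfocal
Title: Quantitative Interictal iEEG Mapping of Epileptic Network Focality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify interictal intracranial EEG (iEEG) and predict
    whether a patient's epileptic network is focal or non-focal. Implements
    clip selection with a wakefulness (alpha/delta ratio) detector, bipolar
    referencing, Butterworth filtering and resampling, Welch relative band
    power and magnitude-squared coherence, z-score abnormality mapping
    against a normative atlas, spatial dispersion statistics over electrode
    coordinates (standard distance and weighted standard distance), and
    cross-validated penalized logistic models that combine iEEG abnormality
    dispersion with a pre-implant clinical score, compared via DeLong's
    test. A synthetic-cohort generator emulates the statistical structure of
    an iEEG surgical-evaluation cohort so the full pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
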