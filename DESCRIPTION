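Package: fetrad
Title: FET-PET Radiomics Pipeline for Recurrent Glioblastoma Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic SUV-threshold tumor segmentation, extraction of a
    135-feature radiomics vector (histogram, shape, GLCM, GLRLM, GLSZM and
    NGTDM texture statistics with equal-probability-quantized and wavelet
    band-pass filtered variants), phantom-based feature robustness screening,
    and prognostic modelling of time-to-progression, overall survival and
    recurrence location (Kaplan-Meier/log-rank, multivariate Cox radiomics
    signatures, imbalance-adjusted bootstrap logistic regression). Includes a
    synthetic-data module that generates tumor-bearing brain PET images,
    NEMA-like sphere phantoms and feature-level outcome cohorts with known
    ground truth, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
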