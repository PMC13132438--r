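Package: pneumabio
Title: Multimodal Digital Biomarkers for Pneumonia Mortality Analysis
Version: 0.1.0
Authors@R:
    person("pneumabio", "developers", email = "pneumabio@example.org",
           role = c("aut", "cre"))
Description: Tools to derive and analyse multimodal digital biomarkers for
    in-hospital pneumonia mortality studies. Includes digitisation of
    rasterised paper electrocardiogram (ECG) pages into calibrated signals,
    Pan-Tompkins beat detection with morphological feature extraction and
    ultra-short heart rate variability metrics, dictionary/regex extraction
    of IDSA/ATS severity criteria from Spanish clinical notes, class
    activation map (CAM) lung-compromise quantification, and an association
    layer (per-SD logistic odds ratios, Firth penalised logistic regression,
    random-intercept mixed models, patient-label permutation tests with
    Benjamini-Hochberg false discovery rate control). A synthetic-data
    module generates every input with known ground truth so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
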