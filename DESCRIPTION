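Package: methylscreen
Title: Discovery and Verification of Blood-Based DNA Methylation Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A genome-scale pipeline for discovering and verifying blood-based
    DNA methylation markers of ovarian cancer. Implements probe filtering and
    tumor-versus-leukocyte separation ranking on Infinium-style beta-value
    matrices, MethyLight-stage counter-screens on cycle thresholds and Percent
    of Methylated Reference (PMR) values, Digital MethyLight molecule counting
    with most-probable-number (Poisson) saturation correction, and longitudinal
    concordance of a serum methylation marker with CA-125 in post-resection
    serial samples (Pearson correlation with significance testing, ROC/AUC
    with stratified bootstrap confidence intervals). Includes a synthetic-data
    module that emulates every input the pipeline consumes, with planted
    ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
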