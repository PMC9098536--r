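Package: gliomark
Title: Multiparametric MRI Differentiation of Glioblastoma from Solitary
    Brain Metastasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volume-of-interest (VOI) based multiparametric MRI analysis for
    separating glioblastoma from single brain metastasis. Implements
    dynamic susceptibility contrast (DSC) perfusion quantification with
    block-circulant SVD deconvolution, percentage signal recovery (PSR),
    apparent diffusion coefficient (ADC) mapping from multi-b diffusion
    weighted imaging, construction of lesion / 5 mm perilesional ring /
    residual edema VOIs via an anisotropic Euclidean distance transform,
    per-case feature extraction, and the ROC-based statistical stage
    (group comparison, Youden cutoffs, maximum-likelihood classifier
    combination, multi-threshold decision rule). Ships digital DSC/DWI
    phantoms and Gaussian feature-cohort simulators so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
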