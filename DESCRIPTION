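Package: csfproxy
Title: MRI-Derived Proxy-Markers of CSF Amyloid and Tau Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Regression of cerebrospinal-fluid (CSF) biomarker concentrations
    (amyloid-beta 1-42, phosphorylated tau 181 and total tau) from 3D
    gray-matter density volumes with compact single-output and multi-output 3D
    convolutional networks, including an average-loss and a weighted
    running-maximum-normalized multi-task loss. Latent embeddings from the
    trained regressors are transferred to Alzheimer's disease diagnostic
    classification and MCI-progression prediction with a regularized logistic
    model, compared against CSF cutoff and exhaustive threshold-sweep
    baselines, and interpreted with integrated-gradients attribution maps,
    group-difference maps and regional summaries. A synthetic cohort generator
    (phenotypes, ROI atlas and volumes with severity-coupled regional atrophy)
    makes the whole pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
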