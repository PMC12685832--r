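Package: coopAS
Title: Cooperative Multimodal Learning for Aortic Stenosis Screening from
    ECG and Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint training of a 12-lead ECG branch (shared per-lead 1-D
    convolutional encoder feeding a Transformer with a class token) and a
    chest-radiograph branch (2-D convolutional network) under a cooperative
    objective: squared-error prediction on the summed branch scores plus a
    rho-weighted agreement penalty on their difference. Includes a synthetic
    paired-cohort generator with a shared latent disease severity, record
    linkage within clinical time windows, patient-level splitting,
    attention-weighted Grad-CAM interpretability, blur-based
    deletion/insertion faithfulness curves with AOPC summaries, and
    bootstrap evaluation statistics for model comparison.
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
    Rcpp,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
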