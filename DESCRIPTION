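Package: flimcontrast
Title: Contrastive Patient Normalization for Multispectral Autofluorescence
    Lifetime Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-stage training framework for automated oral-cancer diagnosis
    and margin delineation from multispectral autofluorescence lifetime
    (maFLIM) pixel decays. Stage one pre-trains a fully connected encoder with
    a supervised contrastive loss built from class anchors and patient-mean
    embeddings, with adaptive clustering and separation weights; stage two
    adds two binary task heads (diagnosis, margin delineation) trained with
    class-weighted cross-entropy and a consistency regularizer. Includes a
    synthetic maFLIM cohort generator with biexponential channel decays and
    patient-level nuisance variability, the full preprocessing chain (median
    filtering, SNR masking, inversion, zero-padding, calibration,
    sum-to-100 normalization), patient-level stratified cross-validation,
    silhouette monitoring, image-level aggregation and evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
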