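Package: vsidiag
Title: Automatic Fetal Presentation, Placental Location and Head Biometry
    from Volume Sweep Imaging Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic interpretation of obstetric volume sweep
    imaging (VSI) examinations: a synthetic sweep-phantom generator with
    known ground truth, frame preprocessing, a trainable U-Net binary
    segmenter for the fetal head and placenta, sweep-indexed spatial
    likelihood maps of the pregnant abdomen, score-based classification of
    fetal presentation and placental location, ellipse-based head biometry
    (biparietal diameter and head circumference) with gestational-age
    estimation, and the inter-rater agreement statistics (Cohen's kappa,
    intraclass correlation, Bland-Altman) used to evaluate such systems.
    Includes a leave-one-out cross-validation harness with rank-based model
    selection and hold-out evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
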