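Package: plusquant
Title: Quantitative Plus-Disease Severity from Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal vessel morphology (dilation, squared-derivative-curvature
    tortuosity, point-based curvature and vessel density) from posterior fundus images
    of premature infants and maps the measurements, via neighborhood component analysis
    feature selection and linear regression, to a continuous Plus-disease severity index
    on a 1-5 scale. Includes contrast-limited adaptive histogram equalisation and
    illumination-correction preprocessing, a patch-trained encoder/decoder vessel
    segmenter with the Tversky loss, boundary-F1 segmentation scoring, multi-expert
    ordinal grading statistics (reference standard diagnosis, linearly weighted kappa,
    per-rater error), and a seeded synthetic vascular phantom generator with analytically
    known morphometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
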