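Package: slicequant
Title: Quantification Pipeline for Irradiated Tissue Slice Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification chain for evaluating tumor and brain
    slice cultures after (proton) irradiation: nucleus segmentation from the
    DAPI channel and gamma-H2AX focus counting as blurred local intensity
    maxima, with area-corrected foci (cfoci) and binary positivity scoring;
    stain-deconvolution based histomorphology fractions (necrosis, DAB/CD44,
    DAPI) and depth-profile assembly; LDH cytotoxicity and resazurin
    (PrestoBlue) plate arithmetic with day-1 normalization; Bland-Altman
    method agreement, Pearson correlation matrices and a slice-clustered
    permutation test; and radiochromic-film dose-map calibration and
    homogeneity QA. A synthetic-data module generates every input with
    machine-readable ground truth so the whole pipeline is testable without
    real specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
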