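Package: punctacall
Title: Puncta Quantification, Binomial Cell Calling and Nested Statistics
    for Multiplexed In Situ Hybridization ROIs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and inference pipeline for multiplexed fluorescent
    in situ hybridization (RNAscope) and immunohistochemistry regions of
    interest: DAPI-based nuclei segmentation with Otsu thresholding,
    per-cell puncta counting and pixel-volume measurement, exact binomial
    per-cell probe-positivity calling with per-ROI Bonferroni correction,
    cell-type classification (cholinergic, glutamatergic, co-labeled),
    Fos-based activation scoring, ROI quality filters (cell-count bounds and
    a conjunctive IQR/z-score outlier rule), and a nested/mixed-effects
    statistical layer that treats ROIs as non-independent replicates within
    mice. Includes a seeded synthetic-ROI generator with full ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
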