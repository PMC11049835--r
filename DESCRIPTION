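Package: spermfish
Title: Sperm Nuclear Architecture from Telomere and Chromosome-Paint FISH Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sperm nuclear architecture from two-dimensional
    fluorescence in situ hybridization (FISH) images: segments the sperm
    nucleus from the counterstain channel, detects the two chromosome-1
    telomere spots, measures the whole-chromosome painting territory, and
    derives the per-cell inter-telomeric distance (ITD, normalized to
    nucleus length) and chromosomal territory area (CTA, normalized to
    nucleus area). Includes a calibrated synthetic FISH-image generator
    with per-cell ground truth for validation, Mann-Whitney group
    comparisons between high- and low-morphology-score sperm, and a
    from-scratch Gini-impurity decision tree classifying cells from
    (ITD, CTA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr,
    optparse
Config/testthat/edition: 3
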