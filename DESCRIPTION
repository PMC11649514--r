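Package: ki67hotspot
Title: Simulation and Method Comparison for Automated Ki67 Hotspot Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic immunohistochemistry slide pairs (Ki67 with a
    CK8/18 serial section) with per-nucleus ground truth, detects and classifies
    tumour nuclei by stain deconvolution and watershed segmentation, restricts
    analysis to invasive tumour with either a serial-section (virtual dual
    staining) mask or a region-based mask, finds the fixed-area Ki67 hotspot
    (0.5 mm2 square containing at least 500 cells) that maximises the
    Ki67-positive ratio, simulates standardized manual 500-cell typewriter
    scoring by two observers, and compares all scoring methods with Spearman
    correlation, Bland-Altman limits of agreement and paired t-tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
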