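Package: mucotrace
Title: Quantifying Motile-Bacteria Penetration into Mucus Droplets from
    Fluorescence Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for ex vivo mucus-barrier assays in which a
    mucus droplet meets a suspension of motile fluorescent bacteria. Computes
    radial fluorescence intensity profiles around an annotated droplet boundary,
    extracts the bacterial penetration length lambda_p by exponential-decay
    fitting, and quantifies size-thresholded bacterial aggregates in concentric
    annular subregions (normalized cluster fraction P1). Includes a synthetic
    fluorescence scene generator with full ground truth that emulates
    low-penetration/exterior-aggregating and high-penetration/interior-aggregating
    phenotypes, exact small-sample nonparametric statistics (enumerated
    Mann-Whitney, Kruskal-Wallis, Grubbs outlier test, curve permutation test),
    and an end-to-end orchestration layer producing tidy long-format tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    mgcv,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
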