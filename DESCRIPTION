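Package: eggquant
Title: High-Throughput Quantification of Drosophila Egg Laying in Multiwell Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for automated quantification of Drosophila melanogaster
    fecundity in 48-well plate assays. Provides snake-path plate addressing and
    four-corner calibration, a synthetic well-image generator with exact ground
    truth, circular well-boundary detection from Canny edges, a deterministic
    star-convex egg detector with score thresholding and non-maximum
    suppression (plus an adapter for external learned segmentation backends),
    area- and boundary-based detection filtering and per-well counting,
    instance-matching evaluation metrics (precision, recall, accuracy, count
    agreement), fecundity statistics with survival-based inclusion rules,
    Bonferroni-corrected pairwise t-tests and a resampling-based downsampling
    power analysis, and chemical dosing arithmetic (serial dilution planning
    and media-concentration to dietary-intake conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
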