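Package: popdemix
Title: Demixed Principal Component Analysis of Neural Population Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population-level analysis of trial-binned firing rates recorded
    under factorial task designs (task parameter x visual condition x time),
    as used for posterior parietal reach-and-grasp recordings. Implements
    ANOVA-style tensor marginalization, demixed principal component analysis
    (dPCA) by per-marginalization reduced-rank ridge regression, signal
    variance accounting with chi-squared comparisons, time-resolved
    cross-validated population decoding with shuffle nulls and a
    minimum-population-size analysis, euclidean-distance discrimination
    time-courses with bootstrap confidence bands and randomization tests,
    and a synthetic pseudo-population generator with analytically planted
    variance structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
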