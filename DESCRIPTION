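Package: dyadsync
Title: Dyadic Movement Synchronization, Complexity and Novelty Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dyadic motion-energy time series from
    mirroring games: movement segmentation by shared stopping points,
    whole-game and per-segment synchronization (Pearson and maximal lagged
    cross-correlation), movement complexity (Shannon entropy of the value
    distribution), segment-wise novelty (Kolmogorov-Smirnov distance to all
    earlier segments), leader-follower classification by bivariate Granger
    causality, regression models of dyadic liking with round-robin
    permutation inference, and median-split time-course comparisons. A
    synthetic-data module generates dyadic signals and liking ratings with
    known ground truth so the whole pipeline is testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
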