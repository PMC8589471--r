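Package: proxigap
Title: Interproximal Contact Morphometry and Food-Impaction Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the interproximal contact geometry of adjacent molars
    from segmented three-dimensional surface point clouds. Extracts five
    morphometric features of the contact region (adjacent line length, adjacent
    surface area, and the tongue, buccal and occlusal abduction-gap angles),
    runs the associated statistical workflow (normality testing, group
    comparison, correlation, principal component analysis with communality
    screening, and binary logistic regression), and scores impaction risk with
    a fixed published logistic model. Ships a synthetic tooth-pair and cohort
    generator with analytically known ground truth so every stage is testable
    without clinical scans, plus readers and writers for labelled STL/PLY
    point-cloud data and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    grDevices,
    jsonlite,
    nortest,
    pracma,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
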