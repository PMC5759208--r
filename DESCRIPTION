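Package: thresher
Title: Cluster Counting with Simultaneous Outlier Removal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Estimates the number of clusters among the objects of a
    variables-by-objects data matrix while detecting and removing outliers.
    Combines an automated Auer-Gervini step-length estimate of the number of
    significant principal components, outlier filtering on the length of
    each object's PCA loading vector, and minimum-BIC von Mises-Fisher
    mixture models fit by EM on the unit hypersphere. Includes
    block-correlation multivariate-normal simulators and the Monte Carlo
    studies used to calibrate the default outlier cutoff and benchmark
    outlier detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
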