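Package: csiscn
Title: Cancer Subtype Identification with Spectral Clustering Using Nystrom
    Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers molecular subtypes from gene-expression profiles with
    spectral clustering accelerated by the Nystrom low-rank approximation.
    Provides microarray-style preprocessing (interquartile-range probe
    collapse, per-gene z-scoring), construction of Gaussian similarity
    blocks over a random landmark set, the one-shot orthogonalized Nystrom
    spectral embedding, Lloyd k-means with a relative-objective stopping
    rule, and survival-driven selection of the Gaussian bandwidth via
    Kaplan-Meier curves, the log-rank test and Mantel-Haenszel hazard
    ratios.  A synthetic-cohort generator with subtype-linked censored
    exponential survival supports end-to-end testing, and a command-line
    interface ties the stages into a train/validate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    survival,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
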