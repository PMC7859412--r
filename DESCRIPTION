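Package: ardkit
Title: Identification of Ageing-Related Diseases from Age-Specific Onset Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying ageing-related diseases (ARDs) from
    aggregated electronic-health-record counts of first recorded diagnoses.
    Computes age-specific rates of disease onset on a fixed 21-84 year grid,
    standardises onset curves, clusters them by hierarchical agglomerative,
    k-means, PAM and spectral methods with a full model-selection procedure
    (cophenetic correlation for linkage choice, the gap statistic for the
    number of clusters, the Dunn index for algorithm choice), and classifies
    each disease's likelihood of being ageing-related by fitting Gompertz and
    exponential-quadratic Gompertz-Makeham models to its onset curve. A
    synthetic cohort generator with known ground-truth curve families makes
    the whole pipeline testable without access-restricted EHR data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
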