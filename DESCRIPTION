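Package: seldistage
Title: Stage Classification of Matrix-Valued SELDI-TOF Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying matrix-valued SELDI-TOF mass-spectrometry
    data points (one n-by-2 matrix of m/z and intensity per sample) into
    Alzheimer's disease stages (control, mild cognitive impairment, total AD).
    Provides peak-list input/output and common-grid alignment, a synthetic
    cohort simulator with tunable class overlap, a Frobenius-distance
    dendrogram baseline, stage eigenmatrix projection with cluster-shrinkage
    quantification, exponential-Euclidean k-nearest-neighbour and Manhattan
    distance voting classifiers, and two-class type-II-error and power
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
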