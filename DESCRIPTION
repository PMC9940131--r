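Package: hybridCRT
Title: Hybrid Sample Size Determination for Parallel-Group and
    Stepped-Wedge Cluster-Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Sample size determination for cluster-randomized trials with a
    continuous outcome when the intra-cluster correlation (ICC) and outcome
    standard deviation are uncertain at the design stage.  Implements
    closed-form treatment-effect variances and one-sided power for
    parallel-group designs and for cross-sectional stepped-wedge designs
    under the Hussey-Hughes model, expected power (assurance over design
    parameters) with truncated-normal, beta, and gamma priors on the ICC
    and standard deviation via quantile-transform Gauss-Legendre quadrature,
    minimal-sample-size search controlling frequentist power or expected
    power, and efficiency comparison of the two designs over grids of
    ICC-prior parameters with equal-expected-power contour extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
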