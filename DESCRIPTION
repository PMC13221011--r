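Package: flowrosetta
Title: Statistical Replication of Flow Cytometry Cell Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analyzes two-dimensional flow-cytometry-style cluster data and
    generates statistically equivalent fully synthetic replicates. Fits
    per-dimension skew-Gaussian and kurtosis-Gaussian mixture models with a
    constrained expectation-maximisation algorithm and BIC model selection,
    extracts principal-axis orientation and distributional parameters, and
    translates them into arguments for a support-line cluster generator.
    Includes corrections for gated (core-clustered) overlapping clusters
    (standard-deviation scaling with doubling, third- and fourth-power moment
    corrections, density adjustment), a dual-pass principal-axis
    skewness-kurtosis covariance (PASKC) replication method, CSV and FCS event
    table input/output, and real-versus-synthetic validation utilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
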