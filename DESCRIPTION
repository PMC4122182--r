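Package: effconn
Title: Multi-Subject Effective Connectivity by Greedy BIC Search and
    Non-Gaussian Edge Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating directed (effective) connectivity among
    brain regions of interest from multi-subject block-design time series.
    Implements condition-wise segmentation of ROI time series, discovery of
    the connection skeleton by greedy forward/backward search maximizing a
    penalized Gaussian likelihood (BIC) averaged across subjects with
    penalty-discount escalation until the first triangle-free graph,
    orientation of every edge of the fixed skeleton by comparing the
    non-Gaussianity of regression residuals with the Anderson-Darling
    statistic pooled across subjects, structural-equation path-coefficient
    estimation per subject with across-subject summaries, and classification
    of connections into "default" and "preparation-related" sub-networks
    across experimental conditions.  A linear non-Gaussian SEM simulator
    with known ground-truth graph sets and block schedules supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr,
    jsonlite
Config/testthat/edition: 3
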