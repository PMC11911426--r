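Package: hdspc
Type: Package
Title: High-Dimensional Nonparametric EWMA Control Charts on Sliding Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Phase-II statistical process control for high-dimensional data
    streams such as multi-analyte blood biomarker panels. Implements the
    D-ELEWMA chart, an exponentially weighted moving average monitor driven by
    a high-dimensional nonparametric empirical-likelihood ratio statistic
    computed on a sliding window, together with the windowed spatial-sign
    MSEWMA comparator chart, Monte-Carlo calibration of control limits to a
    nominal in-control average run length, run-length estimation with
    common-random-number variance reduction, a synthetic in-control and
    shifted-stream generator built from clinical reference ranges, and data
    preparation helpers (missingness filtering, mean imputation, Jarque-Bera
    normality screening, group mean-difference profiling).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
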