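Package: fpemu
Title: Bayesian Estimation of Modern Contraceptive Prevalence from Surveys
    and Family Planning Service Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single-country Bayesian state-space model for annual estimates
    and projections of the modern contraceptive prevalence rate (mCPR) among
    married or in-union women of reproductive age. Total contraceptive
    prevalence and the modern/total ratio follow logistic-growth trends with
    autoregressive time-series distortions; surveys enter through a bivariate
    normal data model on log-ratios, and Estimated Modern Use (EMU) series
    derived from routine service statistics enter through a first-difference
    data model in which annual changes in EMU are unbiased for annual changes
    in mCPR with source-type-specific variance. Includes the source-type
    variance estimator, out-of-sample hold-out validation with coverage,
    error and interval-score metrics, run comparison utilities, a synthetic
    multi-country data generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
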