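Package: impulseWM
Title: Impulse-Perturbation Decoding of Color Working Memory from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-validated Mahalanobis-distance decoding of color working
    memory from epoched EEG, built around the impulse-perturbation ("pinging")
    paradigm. Implements window-of-interest and time-resolved decoding of
    voltage and 8-12 Hz alpha-power patterns with half-cosine basis smoothing
    and shrinkage covariance, representational similarity analysis against
    uniform-circular and primary-color models, sign-flip group permutation
    tests with cluster-based multiple-comparison correction, bootstrap
    confidence intervals, and the behavioral repulsion-bias analysis of
    continuous color reports. A synthetic-data generator produces trial
    tables, multichannel epochs and behavioral reports with the statistical
    structure the analyses assume, so the full pipeline runs and is testable
    without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
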