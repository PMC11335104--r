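Package: occuRange
Title: Two-Scale Species Range Estimation from Niche and Occupancy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the potential and realized geographic distribution of a
    species at two spatial scales. A maximum-entropy ecological niche model
    (linear and quadratic features, L1 regularization, candidate-grid
    evaluation with omission rate, partial ROC and AICc, median consensus and
    percentile-threshold binarization) captures macro-scale suitability; a
    single-season occupancy model with imperfect detection (detection-first
    two-stage AICc selection, parametric-bootstrap chi-squared goodness of
    fit) captures habitat use at survey sites. The two are fused into a
    binary realized-distribution map with area accounting, alongside IUCN
    extent-of-occurrence and area-of-occupancy comparators. A synthetic-data
    module generates spatially autocorrelated covariate rasters, biased
    occurrence samples from a known Gibbs surface, and Bernoulli detection
    histories with known ground truth, so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
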