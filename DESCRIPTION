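Package: mobileqrs
Title: QRS Duration Estimation from Noisy Single-Lead Mobile ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates chest-equivalent QRS durations from low-amplitude,
    motion-artifact-prone single-lead ("mobile") ECG recordings. Implements a
    three-stage pipeline: support-vector-machine heartbeat identification from
    adaptive-threshold spike candidates; QRS boundary localization by multiview
    dynamic time warping (amplitude, first-derivative, and local-angle views)
    against a per-subject heartbeat template learned by K-means++-seeded
    K-medoid (PAM) clustering, with beat-wise distortion scores thresholded by
    the histogram triangle method to purify low-quality beats; and a
    per-subject additive bias calibration mapping mobile-lead durations onto
    the standard chest lead. Ships a synthetic paired chest/mobile ECG
    generator with exact per-beat ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
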