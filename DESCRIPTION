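Package: wcepolyp
Title: Onboard Polyp Detection and Session Simulation for AI Capsule Endoscopy
Version: 0.1.0
Authors@R:
    person("wcepolyp", "maintainers", email = "wcepolyp@example.org",
           role = c("aut", "cre"))
Description: A lightweight 15-layer depthwise-separable grid detector for
    colorectal polyps in 240x240 wireless-capsule-endoscopy frames, together
    with the protocol around it: YOLO-style grid decoding with non-maximum
    suppression, the class-balanced / tenfold-augmented / patient-wise-split
    dataset pipeline, average-precision evaluation at configurable IoU
    thresholds, a seeded synthetic endoscopy frame generator (WLI and NBI
    renderings, cleanliness grades, patient grouping), and a capsule session
    simulator with adaptive frame rate, selective transmission, over-the-air
    network replacement and a two-point power/energy budget model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    png,
    digest,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
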