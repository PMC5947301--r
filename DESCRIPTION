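Package: reachnet
Title: Developmental Reaching and Pointing from Motor Babbling with
    Forward-Inverse Network Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the developmental emergence of reaching and primitive
    pointing in a planar two-joint arm. Motor commands and visual hand
    positions are represented by populations of broadly cosine-tuned units
    (place coding); a simple recurrent network learns the forward
    (motor-to-vision) transformation and a second network learns the inverse
    (vision-to-motor) transformation, both solely from random motor babbling
    with intermittent visual feedback. After learning, coupling the two
    transformations in a loop generates successive motor commands that reach
    toward visually presented targets at within-reach and out-of-reach
    distances, with no hand vision during the movement. Includes the babbling
    trainer (compiled inner loop), one-step forward/inverse probes, the
    reaching-loop simulator, and a runner that reproduces the standard
    experiment tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
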