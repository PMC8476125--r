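Package: replayssm
Title: Switching State-Space Decoding of Hippocampal Replay Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes hippocampal replay during sharp-wave ripples with a
    switching state-space model that estimates, in 2 ms time bins, the joint
    posterior over a latent position on a track graph and a discrete movement
    dynamic (stationary, continuous, or fragmented). Supports encoding models
    for sorted spike trains (penalized Poisson spline GLM place fields) and
    for unsorted spikes with waveform-amplitude marks (kernel joint mark
    intensities), position linearization on track graphs via a Viterbi HMM,
    sharp-wave-ripple and multiunit-burst event detection, five-category
    speed classification with highest-posterior-density summaries, and the
    standard Bayesian-decoder baselines (Radon line fitting, linear
    regression, MAP speed) with shuffle-based significance tests. A
    simulation module generates all inputs synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    splines,
    igraph,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
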