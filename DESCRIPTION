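Package: seqreplay
Title: Sequence Learning and Distracted Rapid Replay in Plastic Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a conductance-based leaky integrate-and-fire recurrent
    network (200 excitatory, 40 inhibitory neurons) equipped with
    nearest-neighbour spike timing-dependent plasticity, synaptic
    normalization, and an adaptive intrinsic firing threshold. The network
    learns a five-element stimulus sequence from repeated Poisson drive,
    rapidly replays it on a cue burst, and is probed with spatio-temporally
    varied distractor bursts. Includes the full evaluation pipeline:
    Gaussian-kernel population rates, windowed peak detection with a
    threshold veto, deviance and disruption indices, weight-category
    analysis of the learned connectivity, and relevant/irrelevant
    distractor classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
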