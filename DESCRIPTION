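Package: twostepSR
Title: Successor-Representation Modelling and Hippocampal LFP Analysis for
    Two-Step Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a successor-representation reinforcement
    learning model of the two-step probabilistic decision task (softmax choice,
    static and windowed maximum a posteriori parameter estimation), and provides
    the matching local field potential analysis chain: synthetic 16-channel LFP
    generation with planted, ground-truth effects; median down-sampling,
    adaptive common average referencing and LMS notch filtering; Morlet
    time-frequency power with baseline normalisation and band averaging;
    representational similarity of temporal context states with
    cluster-permutation contrasts; and links from band power to model-based
    valuations via session-wise regression and choice decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    nortest,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
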