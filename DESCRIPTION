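Package: cascadenet
Title: Collective Decision Dynamics and Information Cascades on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of binary collective decision-making in
    networked groups of naive-Bayesian agents. Implements the synchronous
    scenario, in which agents repeatedly pool neighbours' signed log-odds
    confidences (Weighted Bayes Consensus) or run distributed averaging
    (Belief Consensus), and the asynchronous scenario, in which coupled
    drift-diffusion accumulators broadcast one-shot decisions whose timing is
    converted into confidence-calibrated evidence "kicks" for undecided
    neighbours. Provides random geometric graph topologies with degree
    calibration, Metropolis-Hastings consensus weights and spectral stability
    analysis, analytic first-passage-time machinery for the drift-diffusion
    model with Bayes-risk-optimal thresholds, cascade detection with causal
    attribution, emergent-leader statistics, and reproducible experiment
    drivers with paired-seed comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
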