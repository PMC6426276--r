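Package: routewalk
Title: Biased Random-Walk Routing and Communication Cost on Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A spectrum of routing strategies for weighted undirected
    networks, parameterized by a global-information bias that interpolates
    between unbiased random walks (diffusion) and shortest-path routing.
    Implements target-absorbing biased transition matrices, absorbing-chain
    fundamental matrices, transmission cost (mean walk length) and
    informational cost (Kullback-Leibler divergence from the unbiased walk,
    in bits), degree- and strength-preserving weighted null models with
    simulated-annealing weight assignment, privileged-node hybrid routing
    with walk stretch, trade-off summaries over a lambda grid, and
    deterministic generators of synthetic connectome-like test networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
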