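Package: curveballr
Title: Degree-Preserving Network Randomization with Curveball Trades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Randomizes bipartite, directed and undirected networks while
    preserving every node degree, using Curveball trade Markov chains together
    with classic edge-switching baselines and a size-one-restricted trade chain.
    Includes detection and random re-orientation of non-switchable directed
    3-cycles so the directed sampler covers its full realization space,
    perturbation-score convergence diagnostics, exhaustive enumeration of small
    realization spaces with chi-square uniformity testing, Erdős-Rényi and
    preferential-attachment ensemble generators, plain-text edge-list and
    biadjacency input/output, and a command-line front-end for reproducible
    null-model runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
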