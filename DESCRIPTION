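Package: limnet
Title: Link-Based Influence Maximization on Small Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the link-based influence maximization problem (LIM)
    under the linear threshold diffusion model. A fixed spreader node chooses
    a budget of k nodes to link to; new links open influence paths but dilute
    the relative influence of the targets' other in-neighbours through
    incoming-weight renormalization. Provides the weighted-digraph data model,
    the linear threshold simulator with Monte-Carlo spread estimation, an
    exact spread oracle based on simple-path enumeration with a closed-form
    marginal gain, the GLIM greedy optimizer and centrality/random baselines,
    six synthetic network generators (growing networks plain/with
    redirection/with copying, random-k-out, power-law tree, Barabasi-Albert),
    and an experiment harness producing spread-versus-budget comparison
    curves. Designed for small networks such as inter-organizational
    health-promotion settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
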