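Package: ignitome
Title: Ignition Dynamics and Core Organisation of Weighted Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates deterministic reduced Wong-Wang mean-field dynamics on
    weighted structural connectomes, locates the bistable ignition range under a
    coupling-gain sweep, and relates which nodes ignite (and in what order) to
    the weighted core-shell organisation of the network. Provides weighted
    s-core and k-core decompositions, small-world indices, surrogate-connectome
    null ensembles (homogeneous-weight, degree-preserving rewired, small-world
    matched, weight-permuted), synthetic connectome generators with planted
    strong cores, and bootstrap Spearman rank-correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
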