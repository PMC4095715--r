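Package: mpinet
Title: Network-Based Metabolite Pathway Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pathway identification for metabolomic profiles that accounts
    for the global nonequivalence of metabolites in a functional network and
    for the detection bias of metabolomic technology. Builds an edge-weighted
    metabolite network from chemical-chemical association scores, quantifies
    pairwise global connection strength (GCS) by length-attenuated walk
    counting, summarises each metabolite by its global nonequivalence (GN)
    score, models the probability of a metabolite being reported as
    differential as a monotone function of GN via a penalized constrained
    cubic regression spline, and tests pathways with a Wallenius noncentral
    hypergeometric model whose odds weight derives from the pathway's
    combined global nonequivalence and bias (CGNB) scores. Includes profile
    preprocessing helpers, a seeded synthetic-data generator for end-to-end
    benchmarking, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
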