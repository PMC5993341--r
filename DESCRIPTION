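Package: bhtree
Title: Phylogenetic Tree Simulation Under Generalized Bellman-Harris
    Branching Processes
Version: 1.0.0
Authors@R:
    person("bhtree", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates stochastic phylogenetic trees under a generalized
    Bellman-Harris branching process: per-lineage waiting times to
    speciation and extinction drawn from arbitrary user-specified
    distributions (exponential, Weibull, gamma, uniform, log-normal,
    truncated normal, point mass, or any user callable), symmetric or
    asymmetric (budding) speciation, heritable lineage-specific scaling
    shifts of the waiting-time distributions, stopping on clade age or on
    a number of extant taxa (with the general sampling approach to avoid
    the young-tree bias of first-passage stopping), pruning of extinct
    lineages, and incomplete species sampling (uniform or pendant-branch-
    length-proportional). Special cases include the Yule, constant-rate
    birth-death, and age-dependent speciation and extinction models.
    Trees interoperate with 'ape' and serialize to Newick with per-node
    shift annotations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
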