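Package: coaldelim
Title: Coalescent Simulation and Bayesian Species Delimitation on Inferred Guide Trees
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation toolkit for studying the robustness of Bayesian species
    delimitation to errors in the guide tree. Simulates multilocus sequence data
    under the multispecies coalescent (one fast-evolving mitochondrial locus plus
    nuclear loci, JC69 mutation, strict clock), infers rooted population guide
    trees either by constrained maximum likelihood with midpoint rooting or by
    Bayesian species-tree MCMC under a Yule prior, delimits species on the guide
    tree by reversible-jump MCMC over node collapse/split models, and scores
    clade recovery, false-positive rates and posterior-probability summaries
    across replicates. Includes an exhaustive enumeration-plus-quadrature
    posterior oracle for small problems and property-style validation of all
    probability kernels.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
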