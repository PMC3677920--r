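Package: coevotraits
Title: Correlated Evolution of Discrete Reproductive Traits on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing correlated evolution of discrete characters
    on posterior samples of phylogenetic trees, motivated by the coevolution
    of male nuptial-gift structures and female pregenital barriers in
    leiobunine harvestmen.  Implements constrained continuous-time Markov
    models of trait evolution with a Felsenstein pruning likelihood engine,
    Metropolis-Hastings sampling of transition rates over tree samples,
    stabilized harmonic-mean marginal-likelihood estimation with Bayes
    factors and log-likelihood-ratio model comparison, hierarchical-prior
    ancestral-state reconstruction, stochastic character mapping with
    dwell-time association statistics and predictive-sampling p-values,
    Fitch and Sankoff parsimony with asymmetric (Dollo-style) costs,
    backbone-constraint filtering and maximum-clade-credibility
    summarization of tree samples, and a Yule-process synthetic-data
    generator so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    phangorn
Config/testthat/edition: 3
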