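Package: chromphylo
Title: Chromosome-Number Evolution on Posterior Sets of Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers haploid chromosome-number evolution on rooted
    phylogenetic trees and on posterior tree samples. Implements the
    ChromEvol family of continuous-time Markov models (dysploid gain and
    loss, duplication, demi-duplication, with constant or linear rates),
    ordered ladder Markov models, maximum-likelihood fitting with AIC
    model comparison and Akaike-weight model averaging, ordered Sankoff
    parsimony, marginal ancestral reconstruction, expected event counts
    via stochastic character mapping, fixed-model and reversible-jump
    Bayesian MCMC over rate-class partitions, posterior tree-set
    summaries (majority-rule consensus, maximum clade credibility tree,
    clade-wise integration of reconstructions), and reconstruction
    precision statistics (node-wise and tree-wise precision indices,
    gains-minus-losses distribution summaries with the Chernoff mode
    estimator). A synthetic-data module simulates Yule trees, chromosome
    counts under any of the models, and pseudo-posterior tree sets so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
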