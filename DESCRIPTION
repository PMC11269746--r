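Package: genestream
Title: Convergent Gene-Loss Order and Protein Domain Decay on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-level evolutionary convergence of gene
    repertoires on phylogenies, motivated by the parallel genome reduction of
    fructophilic lactic acid bacteria. Implements binary and k-state Mk
    (continuous-time Markov) models with pruning likelihoods, maximum-likelihood
    fitting, Metropolis MCMC rate sampling and joint/marginal ancestral state
    reconstruction; a gene loss-order similarity statistic with a permutation
    null; rule-based classification of bifunctional-enzyme fragment genes from
    multiple sequence alignments and per-species domain-repertoire states;
    amino-acid ancestral sequence reconstruction with per-branch substitution
    mapping and fragment-specific site enrichment; structure-derived interface
    and ligand-contact annotation; and phylogenetic ANOVA with a
    Brownian-motion simulation null. A synthetic-data module generates every
    input class with known ground truth so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
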