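Package: compshift
Title: Detection of Shifts in Equilibrium Base Composition on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits nonstationary nucleotide substitution models in which
    equilibrium base frequencies shift on edges of a fixed rooted phylogram,
    and locates those shifts with a greedy stepwise search over candidate
    clades scored by the Bayesian Information Criterion. Includes a pruning
    likelihood engine for regime-painted trees (HKY or GTR exchangeabilities,
    optional discrete-gamma rate heterogeneity), BIC-weight support measures
    for the existence and location of each accepted shift, a simulation
    framework for generating alignments under regime-shifted models,
    false-positive and false-negative benchmarking with one-sample t and Z
    tests under false-discovery-rate control, regime-level composition
    summaries (empirical versus equilibrium frequencies, GC content and its
    regression on clade body mass), and a phylogenetic logistic regression of
    shift presence on temporal proximity to a geological boundary using
    terminals grafted onto internal nodes of a chronogram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
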