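Package: paraconv
Title: Detection of Parallel and Convergent Amino Acid Substitutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting molecular convergence between independently
    adapted clades on a phylogeny. Implements marginal ancestral sequence
    reconstruction under the JTT amino-acid model with optional site-specific
    frequencies, enumeration of cross-clade branch-pair comparisons,
    classification of parallel versus convergent substitutions, a
    conservation-pattern (CCS) filter, a profile-shift posterior score for
    convergent preference changes, a Poisson test of observed versus expected
    convergence with Benjamini-Hochberg correction, a codon-level convergent
    rate ratio (omegaC) screen, and a sequence simulator with known ground
    truth for validating the whole cascade, including swapped-outgroup
    control scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
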