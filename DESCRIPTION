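Package: tumorload
Title: Selection Efficiency and Deleterious Load in Tumor Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the efficiency of natural selection in somatic
    evolution. Provides a permutation-based, non-parametric dN/dS estimator
    that preserves gene, sample, base change and trinucleotide context;
    dE/dI selection statistics for copy-number alterations under breakpoint
    and fractional-overlap metrics with a length-preserving permutation
    null; a stochastic birth-death simulator of tumor progression with
    advantageous drivers and deleterious passengers under genome-wide
    linkage; approximate Bayesian computation to infer mean driver and
    passenger fitness effects; and synthetic-data generators with known
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    nnet,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
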