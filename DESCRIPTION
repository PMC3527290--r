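Package: imcoalhmm
Title: Isolation-with-Migration Coalescent Hidden Markov Models for
    Pairwise Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers speciation histories with gene flow from a pairwise
    alignment of one haploid genome per species.  The divergence process is
    modelled as an initial population split followed by a period of symmetric
    migration that later ceases; the ancestry of neighbouring nucleotide pairs
    is tracked by structured-coalescent continuous-time Markov chains from
    which exact transition probabilities between discretized coalescence
    times are derived, yielding a hidden Markov model along the alignment.
    Provides maximum-likelihood estimation of split times, coalescence,
    recombination and migration rates, AIC comparison against a clean-split
    isolation model, posterior decoding of local coalescence times, and an
    exact (non-Markov-approximated) two-deme ancestral recombination graph
    simulator with Jukes-Cantor sequence emission for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
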