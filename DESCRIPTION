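Package: ghostpulse
Title: Structured-Ancestry Coalescent Hidden Markov Models for Ghost
    Admixture Inference from a Diploid Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers an ancestral split-and-rejoin ("pulse") model of
    population structure from a single unphased diploid genome using a
    sequentially Markovian coalescent hidden Markov model.  Two ancestral
    demes A and B separate at a split time and rejoin in a single pulse
    admixture event, with a fraction gamma of present-day lineages deriving
    from the ghost deme B.  The package fits the piecewise population size
    history of A, the size of B, gamma and the recombination rate by
    Baum-Welch expectation-maximization at fixed split/admixture times,
    scans candidate time pairs by composite maximum likelihood, decodes
    per-window posterior probabilities of the ancestral lineage path
    (AA/AB/BB), and provides the identifiability machinery (rate-matched
    panmictic models, relative transition-matrix differences) that
    distinguishes ancestral structure from pure population size change.
    Includes an exact discretized-HMM simulator with recorded truth,
    Monte-Carlo oracles for the analytic transition kernels, readers for
    VCF plus callability masks and psmcfa-style binned sequences, and
    downstream admixture-density and gene-overlap enrichment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml,
    optparse
Config/testthat/edition: 3
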