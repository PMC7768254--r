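Package: ggindel
Title: Pair Hidden Markov Model Approximations to the General Geometric
    Indel Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the general geometric indel (GGI) model of sequence
    evolution: a continuous-time Markov process on sequences in which
    insertions and deletions arrive at rates lambda and mu per site and have
    geometrically distributed lengths with extension probabilities x and y.
    The package numerically integrates a system of ordinary differential
    equations for the expected transition usage of a three-state pair hidden
    Markov model, yielding finite-time alignment transition probabilities
    that reduce exactly to the TKF91 links model when x = y = 0.  It also
    provides the expected-transition-count calculus on weighted state
    machines that the derivation rests on, an exact Gillespie simulator of
    the indel process with run-length-encoded alignment tracking, joint
    gap-length distributions with moments and relative entropy, and forward
    and Viterbi pairwise alignment under the fitted machine, including a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    deSolve,
    graphics,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
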