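Package: stochrob
Title: Robustness Analysis of Stochastic Biochemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Guaranteed lower and upper bounds on time-bounded properties of
    continuous-time Markov chains arising from bounded-population chemical
    reaction networks whose rate constants (and initial states) are uncertain.
    Implements parameterised uniformisation for forward and backward transient
    analysis over boxes of rate constants, min-max evaluation of a bounded-time
    stochastic logic with cumulative rewards and distribution post-processing
    (mean quadratic deviation), adaptive perturbation-space decomposition to a
    requested absolute error, and robustness degrees defined as integrals of
    the evaluation function over the perturbation space. Ships programmatic
    fixtures for a birth-death process, a bistable gene-regulation circuit and
    a two-component signalling pathway.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    ggplot2
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
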