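Package: seqmem
Title: Sequential Memory with Temporal Predictive Coding and Asymmetric
    Hopfield Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models of sequential memory built on temporal predictive
    coding (tPC): a single-layer network that learns pattern-to-pattern
    transitions by minimizing temporal prediction errors with local,
    Hebbian updates, and a two-layer network whose hidden state carries
    temporal context. The Asymmetric Hopfield Network family (identity,
    polynomial and softmax separation) is provided as a baseline under
    the Universal Hopfield retrieval form. Closed-form machinery shows
    that linear tPC retrieval equals Asymmetric Hopfield retrieval with
    a statistically whitened similarity, and experiment drivers measure
    sequence capacity, serial-recall accuracy with primacy/recency
    effects, disambiguation of aliased inputs through hidden context,
    and generalization of learned rotational dynamics. All inputs come
    from seeded synthetic generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
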