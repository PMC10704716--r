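Package: msaextend
Title: Constraint-Preserving Extension of Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adds unaligned query sequences to an existing (backbone)
    multiple sequence alignment without ever altering the backbone.  The
    backbone guide tree is decomposed into small subsets by repeated
    centroid-edge deletion, a profile hidden Markov model is built for
    each induced subalignment, every query is routed to the subalignment
    whose HMM fits best (size-adjusted bitscore), each subalignment is
    extended with its queries under a bounded subproblem size, and the
    extended subalignments are merged by transitivity through shared
    backbone columns.  Also provides a sum-of-pairs alignment error
    scorer (SPFN, SPFP, expansion score) and a sequence evolution
    simulator with heterogeneous indel lengths that tracks the true
    alignment, so the whole pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
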