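Package: ordpair
Title: Monotone Gene-Pair Classifiers for Ordinal Disease Outcomes
Version: 0.1.0
Authors@R:
    person("ordpair", "developers", email = "ordpair@example.org",
           role = c("aut", "cre"))
Description: Exact L1-optimal monotone staircase classifiers on pairs of
    gene-expression features for ordinal outcomes (e.g. short, intermediate
    and long survival). Provides genome-wide gene-pair screening with a
    cross-validation lower-bound preselection heuristic, disjoint-pair
    majority-vote ensembles with ordinal tie-breaking toward the worst
    outcome, ordinal agreement metrics, bootstrap and permutation validation,
    MAD-based gene filtering, stratified splitting, a synthetic data
    generator with planted monotone pairs, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
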