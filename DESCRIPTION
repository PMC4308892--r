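Package: tripiR
Title: Transposon-Interaction Triplet Features for piRNA Classification
Version: 0.1.0
Authors@R:
    person("tripiR", "Maintainers", email = "tripir@example.org", role = c("aut", "cre"))
Description: Classifies candidate PIWI-interacting RNAs (piRNAs) from their
    predicted interaction with transposons. Candidate small RNAs are aligned
    to a transposon library with a mismatch-limited seed-and-verify search,
    the piRNA-transposon RNA duplex is predicted by a deterministic
    dynamic-programming engine, and 32 structure-sequence triplet-element
    frequencies are extracted from the duplex. A radial-basis-function
    support vector machine (trained with a built-in sequential minimal
    optimization solver) separates real from pseudo piRNAs. Includes the
    double-randomization pseudo-piRNA generator with mappability filtering
    and length-distribution matching, a stratified 7/2/1 ten-fold
    cross-validation scheme with grid search, F-value feature ranking,
    ROC/AUC, and deterministic synthetic fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
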