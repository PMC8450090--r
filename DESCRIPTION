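Package: methdecon
Title: Reference-Free Deconvolution of Subpopulation Methylation Profiles
    from Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconvolves per-CpG bisulfite sequencing methylation data from a
    heterogeneous sample into a small number of allelic subpopulations, each
    with a binary methylation profile and a prevalence, over user-defined
    genomic regions. Fits a modified hidden Markov model whose states are
    vectors of per-subpopulation methylation calls, with distance-binned
    transition matrices trained from data and beta-binomial emission
    probabilities for observed methylated read counts; solves each region by
    Viterbi decoding, chooses the number of subpopulations by an iterative
    likelihood-improvement termination rule, and calls and ranks intrasample
    differentially methylated regions (i-DMRs) between the solved profiles.
    Includes mixture simulators (methylation-level and read-level), a
    partial-methylation read classifier, and evaluation utilities for
    comparing solved profiles against reference cell types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
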