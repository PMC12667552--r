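Package: eosqc
Title: Quality Analysis and Information Retrieval for Enzymatic
    Oligonucleotide Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the quality of cycle-by-cycle enzymatic
    oligonucleotide synthesis (EOS) from sequencing reads: a
    synthesis-by-cycle read simulator with per-cycle deletion, insertion
    and substitution probabilities; payload extraction by anchor/polyA
    pattern matching; global alignment to the target with deterministic
    error classification; stepwise and full-length yield statistics; a
    two-bits-to-one-base DNA information-storage codec with global and
    position-conditional majority-vote decoding; and supporting
    enzyme-kinetics calculations (pyrophosphate standard curves, initial
    rates, Michaelis-Menten and Lineweaver-Burk fits, kinetic parameter
    gains, FRET efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
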