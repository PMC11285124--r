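Package: ssvfilter
Title: Single-Segment Ungapped Viterbi Filtering for Nucleotide Profile HMMs
Version: 0.1.0
Authors@R:
    person("ssvfilter", "developers", email = "ssvfilter@example.org",
           role = c("aut", "cre"))
Description: A software implementation of the single-segment ungapped Viterbi
    (SSV) homology filter for nucleotide profile hidden Markov models, the
    first filter stage of the nhmmer search pipeline. Emission scores read
    from HMMER3-format model files are reprojected onto a signed 8-bit scale
    so that a Gumbel P-value threshold maps exactly to an accumulator value
    of 256; the dynamic-programming recurrence is then evaluated with
    reset-on-underflow and hit-plus-reset-on-overflow cell semantics, either
    in plain row-major order or in the segmented column order used by
    systolic-array accelerators. Hits are reported as (sequence, model) cell
    coordinates over concatenated all-to-all databases, resolved back to
    per-record positions, and validated against boundary-crossing artifacts.
    Includes a synthetic model/target/planted-segment generator for
    fixture-based testing and statistical calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
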