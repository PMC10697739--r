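Package: wavealign
Title: Wavefront Pairwise Alignment with Gap-Affine Penalties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact and heuristic global pairwise alignment of DNA sequences
    under gap-affine penalties using the wavefront alignment algorithm.
    Provides bit-parallel match extension over 2-bit-packed sequences, a
    succinct piggybacked backtrace encoding for memory-frugal CIGAR
    recovery, an adaptive banded heuristic, batch alignment with
    score-budgeting and exact rescue, readers and writers for common
    sequence-pair formats, a seedable sequence-pair simulator, and an
    independent full dynamic-programming (Gotoh) reference aligner for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
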