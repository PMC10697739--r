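#' Full dynamic-programming reference alignment (Gotoh)
#'
#' Classical three-matrix gap-affine dynamic programming over the full
#' `(n+1) x (m+1)` matrix: the textbook `O(nm)` algorithm, implemented
#' independently of the wavefront engine and used as the reference oracle in
#' the package's validation suite. Minimisation with match cost 0, mismatch
#' `x`, gap of length `l` costing `o + l * e`.
#'
#' The quadratic memory use limits this aligner to moderate lengths
#' (roughly 10 kb x 10 kb); it is a validation tool, not the production
#' aligner.
#'
#' @inheritParams wfa_align
#' @param mode `"full"` (score and CIGAR) or `"distance"` (score only).
#' @return A list with `score` (integer) and `cigar` (run-length string over
#'   `{M, X, I, D}`, or `NULL` in distance mode).
#' @examples
#' gotoh_align("GATTACA", "GACTACA")  # score 4
#' @export
gotoh_align <- function(query, text, penalties = wfa_penalties(),
                        mode = c("full", "distance")) {
  mode <- match.arg(mode)
  p <- as_penalties(penalties)
  stopifnot(is.character(query), length(query) == 1L,
            is.character(text), length(text) == 1L)
  cpp_gotoh(query, text, p$x, p$o, p$e, want_cigar = (mode == "full"))
}
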