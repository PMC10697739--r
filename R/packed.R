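#' Pack a DNA sequence into 2 bits per base
#'
#' Encodes a DNA string with 2 bits per base into 32-bit words (16 bases per
#' word). The codes are the two distinguishing bits of the ASCII bytes:
#' `A = 00`, `C = 01`, `G = 11`, `T = 10`. Input is upper-cased before
#' packing. In strict mode (default) any character outside `A/C/G/T` is an
#' error naming the offending position; in lenient mode such positions
#' (IUPAC ambiguity codes, `N`, ...) are recorded in a per-sequence exception
#' list and always compare as mismatches in [lcp_packed()].
#'
#' @param seq A single DNA string.
#' @param lenient Map non-ACGT characters to always-mismatching positions
#'   instead of erroring.
#'
#' @return An object of class `"packed_dna"`: a list with `length` (bases),
#'   `words` (integer vector of 32-bit words, 16 bases each plus one guard
#'   word), and `exceptions` (0-based always-mismatch positions).
#' @examples
#' p <- pack_dna("ACGTACGT")
#' unpack_dna(p)
#' @export
pack_dna <- function(seq, lenient = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  structure(cpp_pack(seq, isTRUE(lenient)), class = "packed_dna")
}

#' Decode a packed DNA sequence
#'
#' Inverse of [pack_dna()] for `A/C/G/T`; lenient-mode exception positions
#' decode as `N` (the original ambiguity code is not retained).
#'
#' @param packed A `"packed_dna"` object.
#' @return A DNA string.
#' @export
unpack_dna <- function(packed) {
  stopifnot(inherits(packed, "packed_dna"))
  cpp_unpack(packed)
}

#' Bit-parallel longest common prefix of two packed suffixes
#'
#' Length of the longest common prefix of `a[i..]` and `b[j..]`, comparing
#' blocks of 16 bases at once with 32-bit XOR; the mismatch position within a
#' block is recovered from the lowest set bit pair. Offsets are 0-based
#' counts of already-consumed bases (`0 <= i <= length(a)`), matching the
#' wavefront engine's coordinates. Results are identical to a per-character
#' comparison, including at offsets that are not 16-base aligned; positions
#' on either sequence's exception list never match.
#'
#' @param a,b `"packed_dna"` objects.
#' @param i,j 0-based base offsets into `a` and `b`.
#' @return Integer: the number of matching bases, clamped to the remaining
#'   lengths.
#' @examples
#' a <- pack_dna("ACGTACGTAC")
#' b <- pack_dna("ACGTAAGTAC")
#' lcp_packed(a, b, 0, 0)  # 5
#' @export
lcp_packed <- function(a, b, i = 0L, j = 0L) {
  stopifnot(inherits(a, "packed_dna"), inherits(b, "packed_dna"))
  if (length(i) == 1L && length(j) == 1L)
    cpp_lcp(a, b, as.integer(i), as.integer(j))
  else
    cpp_lcp_many(a, b, as.integer(i), as.integer(j))
}

#' @export
print.packed_dna <- function(x, ...) {
  cat(sprintf("packed_dna: %d bases in %d 32-bit words (%d always-mismatch positions)\n",
              x$length, length(x$words) - 1L, length(x$exceptions)))
  invisible(x)
}
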