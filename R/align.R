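#' Global gap-affine alignment with the wavefront algorithm
#'
#' Aligns `query` against `text` globally under gap-affine penalties by
#' computing wavefronts of furthest-reaching points for increasing score
#' until the match wavefront reaches the bottom-right cell of the DP matrix
#' (offset `m` on diagonal `m - n`). Matches are consumed for free by
#' bit-parallel longest-common-prefix extension over 2-bit-packed sequences;
#' only mismatch and gap transitions increase the score. In `"full"` mode the
#' alignment path is recovered from a succinct piggybacked backtrace (2-bit
#' operation codes in chained 32-bit blocks) and returned as a run-length
#' CIGAR over `{M, X, I, D}`, where `M` is a match, `X` a mismatch, `I`
#' consumes one text character and `D` one query character.
#'
#' With a `band`, each wavefront is clamped to a window of at most `beta`
#' diagonals that is re-centered every `lam` score steps on the most
#' promising diagonal; the result is an upper bound on the exact score
#' (`status = "approximate"`) and is typically exact when the band covers the
#' optimal path. See [band_config()].
#'
#' @param query,text DNA strings (`A/C/G/T`; see `lenient`).
#' @param penalties A [wfa_penalties()] object (or numeric `c(x, o, e)`).
#' @param mode `"full"` (score + CIGAR) or `"distance"` (score only; skips
#'   all backtrace bookkeeping).
#' @param max_score Score budget. If the optimal score exceeds it the
#'   aligner stops and returns `status = "budget_exceeded"` (a typed outcome,
#'   not an error) -- the batch runner uses this for memory budgeting.
#' @param band `NULL` for the exact aligner, or a [band_config()] for the
#'   adaptive banded heuristic.
#' @param lenient Accept non-ACGT characters as always-mismatching positions.
#' @param bt_capacity Maximum number of 32-bit backtrace blocks; exceeding it
#'   yields `status = "bt_overflow"`.
#'
#' @return An object of class `"wfa_alignment"`: a list with
#'   \describe{
#'     \item{score}{Optimal (or banded) alignment cost, `NA` on a typed
#'       failure.}
#'     \item{cigar}{Run-length CIGAR string, or `NULL` in distance mode.}
#'     \item{status}{`"exact"`, `"approximate"`, `"budget_exceeded"`,
#'       `"band_collapse"`, or `"bt_overflow"`.}
#'     \item{stats}{Diagnostics: wavefronts computed, offsets allocated,
#'       maximum wavefront width, backtrace blocks and operations stored,
#'       highest score reached.}
#'   }
#' @examples
#' wfa_align("GATTACA", "GACTACA")
#' wfa_align("AAAA", "AAAAA", wfa_penalties(4, 6, 2))$cigar
#' @export
wfa_align <- function(query, text, penalties = wfa_penalties(),
                      mode = c("full", "distance"), max_score = Inf,
                      band = NULL, lenient = FALSE, bt_capacity = Inf) {
  mode <- match.arg(mode)
  p <- as_penalties(penalties)
  stopifnot(is.character(query), length(query) == 1L, !is.na(query),
            is.character(text), length(text) == 1L, !is.na(text))
  if (!is.null(band) && !inherits(band, "wfa_band_config"))
    stop("`band` must be NULL or a band_config() object")
  banded <- !is.null(band)
  res <- cpp_wf_align(query, text, p$x, p$o, p$e,
                      want_cigar = (mode == "full"),
                      max_score = if (is.finite(max_score)) as.double(max_score) else -1,
                      banded = banded,
                      beta = if (banded) band$beta else 0L,
                      lam = if (banded) band$lam else 0L,
                      center_target = if (banded) band$center == "target" else FALSE,
                      lenient = isTRUE(lenient),
                      bt_capacity = as.double(bt_capacity))
  structure(list(score = res$score, cigar = res$cigar, status = res$status,
                 stats = res$stats, penalties = p),
            class = "wfa_alignment")
}

#' Alignment distance only
#'
#' Convenience wrapper for [wfa_align()] in `"distance"` mode: computes the
#' optimal gap-affine cost without any backtrace bookkeeping.
#'
#' @inheritParams wfa_align
#' @return A `"wfa_alignment"` object with `cigar = NULL`.
#' @export
wfa_distance <- function(query, text, penalties = wfa_penalties(),
                         max_score = Inf, band = NULL, lenient = FALSE) {
  wfa_align(query, text, penalties, mode = "distance", max_score = max_score,
            band = band, lenient = lenient)
}

#' @export
print.wfa_alignment <- function(x, ...) {
  cat(sprintf("wavefront alignment [%s]\n", x$status))
  if (!is.na(x$score)) cat(sprintf("  score: %d\n", x$score))
  if (!is.null(x$cigar)) cat(sprintf("  cigar: %s\n", x$cigar))
  cat(sprintf("  wavefronts: %d, max width: %d, backtrace blocks: %d\n",
              x$stats$wavefronts, x$stats$max_width, x$stats$bt_blocks))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CIGAR utilities
# ---------------------------------------------------------------------------

#' Parse a run-length CIGAR
#'
#' @param cigar A CIGAR string over `{M, X, I, D}` (e.g. `"2M1X4M"`).
#' @return A data.frame with columns `len` (integer) and `op` (character),
#'   one row per run.
#' @export
cigar_ops <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (!nzchar(cigar)) return(data.frame(len = integer(), op = character()))
  runs <- regmatches(cigar, gregexpr("([0-9]+)([MXID])", cigar))[[1]]
  if (sum(nchar(runs)) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  data.frame(len = as.integer(sub("[MXID]$", "", runs)),
             op = sub("^[0-9]+", "", runs),
             stringsAsFactors = FALSE)
}

#' Re-score a CIGAR under gap-affine penalties
#'
#' Each `M` run is free, each `X` position costs `x`, and each maximal `I` or
#' `D` run of length `l` costs `o + l * e`. For CIGARs produced by
#' [wfa_align()] or [gotoh_align()] this reproduces the reported score
#' exactly.
#'
#' @inheritParams cigar_ops
#' @param penalties A [wfa_penalties()] object.
#' @return Integer score.
#' @export
cigar_score <- function(cigar, penalties = wfa_penalties()) {
  p <- as_penalties(penalties)
  ops <- cigar_ops(cigar)
  if (nrow(ops) == 0L) return(0L)
  gap <- ops$op %in% c("I", "D")
  sum(ops$len[ops$op == "X"]) * p$x +
    sum(gap) * p$o + sum(ops$len[gap]) * p$e
}

#' Characters consumed by a CIGAR
#'
#' @inheritParams cigar_ops
#' @return Named integer vector `c(query = , text = )`: `M`/`X` consume one
#'   character of each sequence, `I` one text character, `D` one query
#'   character.
#' @export
cigar_consumed <- function(cigar) {
  ops <- cigar_ops(cigar)
  c(query = sum(ops$len[ops$op %in% c("M", "X", "D")]),
    text = sum(ops$len[ops$op %in% c("M", "X", "I")]))
}

#' Collapse a CIGAR to SAM-like M
#'
#' Merges `M` (match) and `X` (mismatch) runs into plain `M`, as SAM-style
#' CIGARs do. The collapsed form is lossy for re-scoring.
#'
#' @inheritParams cigar_ops
#' @return A CIGAR string over `{M, I, D}`.
#' @export
cigar_samlike <- function(cigar) {
  ops <- cigar_ops(cigar)
  if (nrow(ops) == 0L) return("")
  ops$op[ops$op == "X"] <- "M"
  keep <- c(TRUE, ops$op[-1L] != ops$op[-nrow(ops)])
  grp <- cumsum(keep)
  len <- tapply(ops$len, grp, sum)
  op <- ops$op[keep]
  paste0(as.integer(len), op, collapse = "")
}
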