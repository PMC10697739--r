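#' Conservative score budget for a pair of lengths
#'
#' Converts an assumed maximum error rate into a score budget: the cost of
#' `ceil(max_error_rate * max(n, m))` worst-case single-character edits
#' (each at most `max(x, o + e)`) plus, when the lengths differ, one gap
#' covering the length difference. Alignments whose true score is within the
#' budget are never rescued; the batch runner pre-allocates memory from
#' [estimate_memory()] evaluated at this budget.
#'
#' @param n,m Query and text lengths.
#' @param penalties A [wfa_penalties()] object.
#' @param max_error_rate Assumed maximum error rate, in `(0, 1]`
#'   (default 0.10).
#' @return Integer score budget, `>= 0`.
#' @examples
#' score_budget(100, 100, wfa_penalties(4, 6, 2))  # 10 * 8 = 80
#' @export
score_budget <- function(n, m, penalties = wfa_penalties(),
                         max_error_rate = 0.10) {
  stopifnot(n >= 0, m >= 0, max_error_rate > 0, max_error_rate <= 1)
  p <- as_penalties(penalties)
  edits <- ceiling(max_error_rate * pmax(n, m))
  as.integer(edits * max(p$x, p$o + p$e) +
               ifelse(n != m, p$o + abs(n - m) * p$e, 0L))
}

#' Batch alignment with budgeting and rescue
#'
#' Aligns every pair under a per-alignment score budget derived from
#' `max_error_rate` (see [score_budget()]). Pairs that exceed their budget --
#' or whose band collapses or backtrace buffer overflows in `"approx"` mode
#' -- are re-run by the unbounded exact aligner and marked
#' `status = "rescued"`, so in `"exact"` mode every final score is optimal.
#' Input order is preserved and results are deterministic for any worker
#' count (alignment uses no randomness). Pairs whose sequences fail
#' validation are reported with `status = "error"` rather than aborting the
#' batch.
#'
#' @param pairs A data.frame of pair records with columns `query` and `text`
#'   (and optionally `id`), e.g. from [read_seq_pairs()] or
#'   [simulate_pairs()].
#' @param penalties A [wfa_penalties()] object.
#' @param mode `"exact"` or `"approx"` (banded heuristic).
#' @param distance_only Skip CIGARs and all backtrace bookkeeping.
#' @param max_error_rate Assumed maximum error rate for the score budget.
#' @param band A [band_config()], used when `mode = "approx"`.
#' @param batch_size Pairs processed per internal chunk (bounds memory).
#' @param workers Parallel workers (forked via [parallel::mclapply()]).
#' @param lenient Accept non-ACGT characters as always-mismatching positions.
#'
#' @return An object of class `"wfa_batch_report"`: a list with
#'   `results` (data.frame `id`, `score`, `cigar`, `status`, input order),
#'   `counters` (`total`, `rescued`, `band_collapsed`, `errors`) and
#'   `rescue_fraction`.
#' @examples
#' pairs <- simulate_pairs(4, 60, 0.05, seed = 1)
#' align_batch(pairs)
#' @export
align_batch <- function(pairs, penalties = wfa_penalties(),
                        mode = c("exact", "approx"), distance_only = FALSE,
                        max_error_rate = 0.10, band = band_config(),
                        batch_size = 512L, workers = 1L, lenient = FALSE) {
  mode <- match.arg(mode)
  p <- as_penalties(penalties)
  stopifnot(is.data.frame(pairs), all(c("query", "text") %in% names(pairs)),
            batch_size >= 1L, workers >= 1L)
  ids <- if ("id" %in% names(pairs)) as.character(pairs$id)
         else sprintf("pair_%d", seq_len(nrow(pairs)))
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_dup")
  use_band <- if (mode == "approx") band else NULL
  align_mode <- if (distance_only) "distance" else "full"

  one <- function(i) {
    q <- pairs$query[i]; t <- pairs$text[i]
    tryCatch({
      budget <- score_budget(nchar(q), nchar(t), p, max_error_rate)
      res <- wfa_align(q, t, p, mode = align_mode, max_score = budget,
                       band = use_band, lenient = lenient)
      collapsed <- res$status == "band_collapse"
      if (res$status %in% c("budget_exceeded", "band_collapse", "bt_overflow")) {
        res <- wfa_align(q, t, p, mode = align_mode, lenient = lenient)
        res$status <- "rescued"
      }
      list(score = res$score, cigar = res$cigar, status = res$status,
           collapsed = collapsed)
    }, error = function(e) {
      list(score = NA_integer_, cigar = NULL,
           status = paste0("error: ", conditionMessage(e)), collapsed = FALSE)
    })
  }

  rows <- vector("list", nrow(pairs))
  idx <- seq_len(nrow(pairs))
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    rows[chunk] <- if (workers > 1L)
      parallel::mclapply(chunk, one, mc.cores = workers)
    else
      lapply(chunk, one)
  }

  status <- vapply(rows, function(r) r$status, character(1))
  results <- data.frame(
    id = ids,
    score = vapply(rows, function(r) as.integer(r$score), integer(1)),
    cigar = vapply(rows, function(r)
      if (is.null(r$cigar)) NA_character_ else r$cigar, character(1)),
    status = status,
    stringsAsFactors = FALSE)
  counters <- list(
    total = nrow(pairs),
    rescued = sum(status == "rescued"),
    band_collapsed = sum(vapply(rows, function(r) r$collapsed, logical(1))),
    errors = sum(startsWith(status, "error")))
  structure(list(results = results, counters = counters,
                 rescue_fraction = if (nrow(pairs)) counters$rescued / nrow(pairs) else 0),
            class = "wfa_batch_report")
}

#' @export
print.wfa_batch_report <- function(x, ...) {
  cat(sprintf("wavefront batch report: %d pairs, %d rescued (%.2f%%), %d band-collapsed, %d errors\n",
              x$counters$total, x$counters$rescued, 100 * x$rescue_fraction,
              x$counters$band_collapsed, x$counters$errors))
  if (nrow(x$results)) print(utils::head(x$results, 10L))
  if (nrow(x$results) > 10L) cat(sprintf("... %d more rows\n", nrow(x$results) - 10L))
  invisible(x)
}
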