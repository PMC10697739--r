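#' Read sequence pairs from the two-line "seq" format
#'
#' The "seq" dialect stores one pair per two lines: a pattern (query) line
#' prefixed `>` followed by a text line prefixed `<`. Records are returned in
#' file order with auto-numbered ids; malformed lines are reported with their
#' 1-based line numbers. Non-ASCII content is rejected.
#'
#' @param path Path to a "seq" file.
#' @return A data.frame of pair records (`id`, `query`, `text`); zero rows
#'   for an empty file.
#' @examples
#' f <- tempfile(fileext = ".seq")
#' writeLines(c(">ACGT", "<ACGT"), f)
#' read_seq_pairs(f)
#' @export
read_seq_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parse_seq_lines(lines, first_line = 1L)
}

parse_seq_lines <- function(lines, first_line) {
  if (length(lines) == 0L)
    return(data.frame(id = character(), query = character(),
                      text = character(), stringsAsFactors = FALSE))
  bad <- which(!validEnc(lines) | grepl("[^\x01-\x7F]", lines, useBytes = TRUE))
  if (length(bad))
    stop(sprintf("line %d: non-ASCII content", first_line + bad[1] - 1L))
  if (length(lines) %% 2L == 1L)
    stop(sprintf("line %d: query line without a partner text line",
                 first_line + length(lines) - 1L))
  qi <- seq(1L, length(lines), by = 2L)
  ti <- qi + 1L
  badq <- qi[!startsWith(lines[qi], ">")]
  if (length(badq))
    stop(sprintf("line %d: expected a query line starting with '>'",
                 first_line + badq[1] - 1L))
  badt <- ti[!startsWith(lines[ti], "<")]
  if (length(badt))
    stop(sprintf("line %d: expected a text line starting with '<'",
                 first_line + badt[1] - 1L))
  data.frame(id = sprintf("pair_%d", (first_line - 1L) %/% 2L + seq_along(qi)),
             query = substring(lines[qi], 2L),
             text = substring(lines[ti], 2L),
             stringsAsFactors = FALSE)
}

#' Read sequence pairs from two parallel FASTA files
#'
#' Records are paired by order: the i-th query record aligns against the i-th
#' text record. Multi-line (wrapped) FASTA parses identically to unwrapped.
#' Ids are taken from the query record names (auto-numbered if absent or
#' duplicated).
#'
#' @param query_path,text_path Paths to FASTA files with equal record counts.
#' @return A data.frame of pair records (`id`, `query`, `text`).
#' @export
read_fasta_pairs <- function(query_path, text_path) {
  q <- Biostrings::readBStringSet(query_path)
  t <- Biostrings::readBStringSet(text_path)
  if (length(q) != length(t))
    stop(sprintf("record count mismatch: %d query vs %d text records",
                 length(q), length(t)))
  ids <- names(q)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    ids <- sprintf("pair_%d", seq_along(q))
  data.frame(id = ids, query = as.character(q), text = as.character(t),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a batch report as TSV
#'
#' One row per pair in input order with columns `id`, `score`, `cigar`
#' (`-` when absent, e.g. distance-only mode) and `status`, plus a header
#' row. A summary footer (totals and rescue fraction) goes to the log via
#' [message()], not into the file, so the TSV round-trips.
#'
#' @param report A `"wfa_batch_report"` from [align_batch()].
#' @param path Output file path.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "wfa_batch_report"))
  out <- report$results
  out$cigar[is.na(out$cigar)] <- "-"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("wrote %d alignments: %d rescued (%.3f%%), %d errors",
                  report$counters$total, report$counters$rescued,
                  100 * report$rescue_fraction, report$counters$errors))
  invisible(report)
}

#' Read a batch report written by [write_report()]
#'
#' @param path Path to a TSV report.
#' @return A data.frame with columns `id`, `score`, `cigar` (`NA` where the
#'   file holds `-`), `status`.
#' @export
read_report <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character", cigar = "character"))
  out$cigar[out$cigar == "-"] <- NA_character_
  out
}

#' Stream a "seq" file through the batch aligner
#'
#' Reads the two-line pair format in chunks of `batch_size` pairs through a
#' connection, aligns each chunk with [align_batch()], and appends results to
#' `output` as TSV, so memory is bounded by the chunk size rather than the
#' file size.
#'
#' @inheritParams align_batch
#' @param path Input "seq" file.
#' @param output Output TSV path.
#' @param ... Passed to [align_batch()].
#' @return A `"wfa_batch_report"` with the concatenated results and pooled
#'   counters, invisibly.
#' @export
align_batch_file <- function(path, output, batch_size = 512L, ...) {
  con <- file(path, "r")
  on.exit(close(con))
  first <- TRUE
  line_no <- 1L
  all_results <- list()
  counters <- list(total = 0L, rescued = 0L, band_collapsed = 0L, errors = 0L)
  repeat {
    lines <- readLines(con, n = 2L * batch_size, warn = FALSE)
    if (length(lines) == 0L) break
    pairs <- parse_seq_lines(lines, first_line = line_no)
    line_no <- line_no + length(lines)
    rep <- align_batch(pairs, batch_size = batch_size, ...)
    chunk_out <- rep$results
    chunk_out$cigar[is.na(chunk_out$cigar)] <- "-"
    write.table(chunk_out, output, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = first,
                append = !first)
    first <- FALSE
    all_results[[length(all_results) + 1L]] <- rep$results
    for (f in names(counters)) counters[[f]] <- counters[[f]] + rep$counters[[f]]
  }
  if (first)  # empty input: still emit a header
    write.table(data.frame(id = character(), score = integer(),
                           cigar = character(), status = character()),
                output, sep = "\t", quote = FALSE, row.names = FALSE)
  results <- if (length(all_results)) do.call(rbind, all_results)
             else data.frame(id = character(), score = integer(),
                             cigar = character(), status = character(),
                             stringsAsFactors = FALSE)
  invisible(structure(
    list(results = results, counters = counters,
         rescue_fraction = if (counters$total) counters$rescued / counters$total else 0),
    class = "wfa_batch_report"))
}

#' Write sequence pairs in the two-line "seq" format
#'
#' @param pairs A data.frame with columns `query` and `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seq_pairs <- function(pairs, path) {
  stopifnot(is.data.frame(pairs), all(c("query", "text") %in% names(pairs)))
  lines <- character(2L * nrow(pairs))
  if (nrow(pairs)) {
    lines[seq(1L, length(lines), by = 2L)] <- paste0(">", pairs$query)
    lines[seq(2L, length(lines), by = 2L)] <- paste0("<", pairs$text)
  }
  writeLines(lines, path)
  invisible(path)
}
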