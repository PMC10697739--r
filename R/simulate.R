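#' Simulate pairs of sequences with injected edits
#'
#' Generates benchmark pairs the way wavefront-aligner evaluations build
#' their simulated datasets: for each pair a uniform random base sequence of
#' the requested length is drawn as the text, and the query is derived by
#' injecting `round(error_rate * length)` edits (or a Poisson-distributed
#' count with that mean, with `count_model = "poisson"`) at uniform random
#' positions, mixing mismatches, insertions and deletions in the `op_mix`
#' proportions. Mismatch and deletion positions are drawn without
#' replacement (collisions re-positioned by the sampling itself), and a
#' mismatch always substitutes a different base, so the nominal edit count is
#' realised. The injected edit count is recorded in each record id.
#'
#' @param n_pairs Number of pairs.
#' @param length Text length in bases.
#' @param error_rate Fraction of the length to inject as edits, in `[0, 1]`.
#' @param op_mix Proportions of mismatch/insertion/deletion among injected
#'   edits; normalised to sum to 1.
#' @param seed Optional integer seed (sets R's RNG); identical seeds give
#'   byte-identical batches.
#' @param count_model `"fixed"` (exactly `round(error_rate * length)` edits
#'   per pair) or `"poisson"` (per-pair count drawn with that mean).
#'
#' @return A data.frame of pair records with columns `id`, `query`, `text`,
#'   `edits` (injected edit count).
#' @examples
#' simulate_pairs(2, 30, 0.1, seed = 7)
#' @export
simulate_pairs <- function(n_pairs, length, error_rate,
                           op_mix = c(mismatch = 1, insertion = 1, deletion = 1) / 3,
                           seed = NULL, count_model = c("fixed", "poisson")) {
  count_model <- match.arg(count_model)
  stopifnot(n_pairs >= 0, length >= 0,
            error_rate >= 0, error_rate <= 1,
            length(op_mix) == 3L, all(op_mix >= 0), sum(op_mix) > 0)
  op_mix <- op_mix / sum(op_mix)
  if (!is.null(seed)) set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  nominal <- round(error_rate * length)

  recs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    text <- sample(bases, length, replace = TRUE)
    k <- if (count_model == "poisson") rpois(1L, nominal) else nominal
    k <- min(k, length)  # at most one mismatch/deletion per position
    types <- if (k > 0)
      sample(c("X", "I", "D"), k, replace = TRUE, prob = op_mix)
    else character()
    n_x <- sum(types == "X"); n_d <- sum(types == "D"); n_i <- sum(types == "I")

    query <- text
    # distinct text positions for substitutions and deletions
    pos <- if (n_x + n_d > 0) sample.int(length, n_x + n_d) else integer()
    xpos <- pos[seq_len(n_x)]
    dpos <- pos[n_x + seq_len(n_d)]
    for (px in xpos)
      query[px] <- sample(bases[bases != text[px]], 1L)
    if (n_d > 0) query[dpos] <- NA_character_
    if (n_i > 0) {
      # insertion gaps 0..length (before position g + 1)
      gaps <- sample(0:length, n_i, replace = TRUE)
      ins <- split(sample(bases, n_i, replace = TRUE), gaps)
      out <- character(0)
      if (!is.null(ins[["0"]])) out <- ins[["0"]]
      for (px in seq_len(length)) {
        out <- c(out, query[px])
        g <- as.character(px)
        if (!is.null(ins[[g]])) out <- c(out, ins[[g]])
      }
      query <- out
    }
    query <- query[!is.na(query)]
    recs[[i]] <- data.frame(
      id = sprintf("sim_%d_e%d", i, k),
      query = paste(query, collapse = ""),
      text = paste(text, collapse = ""),
      edits = as.integer(k),
      stringsAsFactors = FALSE)
  }
  if (n_pairs == 0)
    return(data.frame(id = character(), query = character(),
                      text = character(), edits = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}
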