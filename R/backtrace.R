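#' Succinct backtrace buffer
#'
#' The aligner stores backtrace information as 2-bit operation codes
#' (`X`, `I`, `D`; matches are never stored) packed 16 to a 32-bit BT-block.
#' When a diagonal's active block fills up it is offloaded to a global
#' append-only BT-buffer and the fresh block keeps the index of its
#' predecessor, chaining blocks backwards. Offloaded blocks are immutable, so
#' two diagonals inheriting from one winner share the frozen prefix chain
#' while extending independent active blocks (copy-on-extend).
#'
#' These functions expose the store for inspection and testing; [wfa_align()]
#' drives the same machinery internally.
#'
#' @param capacity Maximum number of blocks the buffer may hold; exceeding it
#'   is a typed overflow (`"wfa_bt_overflow"` condition), which the batch
#'   runner converts into a rescue.
#' @return `bt_buffer()` returns an external pointer of class
#'   `"wfa_bt_buffer"`; `bt_handle()` an empty backtrace handle.
#' @examples
#' buf <- bt_buffer()
#' h <- bt_handle()
#' h <- bt_push_op(h, "X", buf)
#' h <- bt_push_op(h, "I", buf)
#' bt_traceback(buf, h)
#' @export
bt_buffer <- function(capacity = Inf) {
  ptr <- cpp_bt_buffer_new(as.double(capacity))
  class(ptr) <- "wfa_bt_buffer"
  ptr
}

#' @rdname bt_buffer
#' @export
bt_handle <- function() {
  structure(cpp_bt_handle_new(), class = "wfa_bt_handle")
}

#' @rdname bt_buffer
#' @param buf A [bt_buffer()].
#' @export
bt_buffer_size <- function(buf) {
  stopifnot(inherits(buf, "wfa_bt_buffer"))
  cpp_bt_buffer_size(buf)
}

bt_op_codes <- c(X = 1L, I = 2L, D = 3L)

#' Append a backtrace operation (copy-on-extend)
#'
#' Appends one edit operation to a handle's active block, offloading the
#' block to `buf` first if it already holds 16 operations. The input handle
#' is never mutated; the extended handle is returned, so handles behave as
#' values and chains can be shared safely.
#'
#' @param handle A [bt_handle()] (or a handle returned by this function).
#' @param op `"X"`, `"I"`, or `"D"` (codes 1, 2, 3; matches are not stored).
#' @param buf A [bt_buffer()].
#' @return The extended handle. Signals a condition of class
#'   `"wfa_bt_overflow"` if the buffer capacity is exhausted.
#' @export
bt_push_op <- function(handle, op, buf) {
  stopifnot(inherits(handle, "wfa_bt_handle"), inherits(buf, "wfa_bt_buffer"))
  code <- if (is.character(op)) bt_op_codes[[match.arg(op, c("X", "I", "D"))]]
          else as.integer(op)
  out <- cpp_bt_push(unclass(handle), code, buf)
  if (isTRUE(out$overflow))
    stop(structure(class = c("wfa_bt_overflow", "error", "condition"),
                   list(message = "backtrace buffer capacity exhausted",
                        call = sys.call())))
  out$overflow <- NULL
  structure(out, class = "wfa_bt_handle")
}

#' Recover the edit operations behind a handle
#'
#' Walks the chained BT-blocks backwards from `handle` and returns all edit
#' operations in emission (alignment) order.
#'
#' @inheritParams bt_push_op
#' @return Character vector over `{"X", "I", "D"}`.
#' @export
bt_traceback <- function(buf, handle) {
  stopifnot(inherits(buf, "wfa_bt_buffer"), inherits(handle, "wfa_bt_handle"))
  codes <- cpp_bt_traceback(buf, unclass(handle))
  names(bt_op_codes)[codes]
}

#' Rebuild a full CIGAR from edit operations
#'
#' Interleaves the stored edit operations with match runs recomputed by the
#' same LCP function the aligner uses: matches are consumed until the next
#' edit position, the edit is applied, and the process repeats. The operation
#' list must consume the two sequences exactly.
#'
#' @param ops Character (or code) vector of edit operations in alignment
#'   order, e.g. from [bt_traceback()].
#' @param query,text The aligned DNA strings.
#' @param lenient Accept non-ACGT characters as always-mismatching positions.
#' @return A run-length CIGAR string over `{M, X, I, D}`.
#' @examples
#' reconstruct_cigar("X", "GATTACA", "GACTACA")  # "2M1X4M"
#' @export
reconstruct_cigar <- function(ops, query, text, lenient = FALSE) {
  codes <- if (is.character(ops)) bt_op_codes[ops] else as.integer(ops)
  if (length(codes) && anyNA(codes)) stop("ops must be X, I or D")
  cpp_build_cigar(as.integer(codes), query, text, isTRUE(lenient))
}

#' Operations per backtrace block
#'
#' Number of 2-bit operation codes that fit in one 32-bit BT-block.
#'
#' @return Integer (16).
#' @export
bt_block_capacity <- function() {
  cpp_bt_block_ops()
}

#' Succinct-backtrace storage accounting
#'
#' Reports the storage geometry of the piggybacked backtrace encoding -- how
#' many operations fit in one BT-block, the amortised bits consumed per
#' wavefront entry (2-bit code plus the entry's share of the 32-bit
#' previous-block index), and the reduction relative to storing raw 4-byte
#' wavefront offsets for every score, as a classical full-history
#' implementation must. When an alignment is supplied, the realised byte
#' counts of its run are included: succinct bytes actually offloaded versus
#' the raw-offset bytes its wavefronts would have needed, and the analytic
#' upper bound from [estimate_memory()].
#'
#' @param alignment Optional `"wfa_alignment"` from a `"full"`-mode run.
#' @return A list with `ops_per_block`, `bits_per_entry`,
#'   `raw_bits_per_entry`, `reduction`, and (given an alignment)
#'   `run` diagnostics.
#' @export
storage_audit <- function(alignment = NULL) {
  ops_per_block <- cpp_bt_block_ops()               # 32-bit block / 2-bit op
  block_bits <- 32L
  index_bits <- 32L                                 # previous-block index
  out <- list(
    ops_per_block = ops_per_block,
    bits_per_entry = (block_bits + index_bits) / ops_per_block,
    raw_bits_per_entry = 32L,                       # 4-byte raw offset
    reduction = 32L * ops_per_block / (block_bits + index_bits))
  if (!is.null(alignment)) {
    stopifnot(inherits(alignment, "wfa_alignment"))
    st <- alignment$stats
    est <- estimate_memory(st$max_score_reached)
    out$run <- list(
      score = st$max_score_reached,
      offsets_allocated = st$offsets_allocated,
      offsets_bound = est$offsets,
      bytes_raw_bound = est$bytes_raw,
      bt_blocks = st$bt_blocks,
      bytes_succinct = st$bt_blocks * (block_bits + index_bits) / 8)
  }
  out
}

#' Worst-case wavefront memory for a given score
#'
#' A full-history wavefront alignment reaching score `s` stores at most
#' `3 * sum_{i=0}^{s} (1 + 2i) = 3 * (s + 1)^2` offsets across the three
#' components, i.e. `12 * (s + 1)^2` bytes at 4 bytes per raw offset. This
#' bound drives the batch runner's pre-allocation via [score_budget()].
#'
#' @param s Alignment score(s), integer `>= 0`.
#' @return A list with `offsets = 3 * (s + 1)^2` and
#'   `bytes_raw = 12 * (s + 1)^2`, vectorised over `s`.
#' @examples
#' estimate_memory(9)  # 300 offsets, 1200 bytes
#' @export
estimate_memory <- function(s) {
  stopifnot(all(s >= 0))
  list(offsets = 3 * (s + 1)^2, bytes_raw = 12 * (s + 1)^2)
}
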