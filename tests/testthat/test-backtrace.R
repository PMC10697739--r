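test_that("a BT-block holds 16 ops and offloads with a chained predecessor", {
  expect_identical(bt_block_capacity(), 16L)
  buf <- bt_buffer()
  h <- bt_handle()
  for (i in 1:16) h <- bt_push_op(h, "X", buf)
  expect_identical(bt_buffer_size(buf), 0)   # active block just filled
  h <- bt_push_op(h, "I", buf)               # 17th op triggers the offload
  expect_identical(bt_buffer_size(buf), 1)
  expect_identical(h$count, 1L)
  expect_true(h$prev >= 0)
})

test_that("traceback round-trips pushed ops in emission order", {
  buf <- bt_buffer()
  expect_identical(bt_traceback(buf, bt_handle()), character(0))

  set.seed(808)
  for (rep in 1:5) {
    ops <- sample(c("X", "I", "D"), 40, replace = TRUE)
    h <- bt_handle()
    for (op in ops) h <- bt_push_op(h, op, buf)
    expect_identical(bt_traceback(buf, h), ops)
  }
})

test_that("copy-on-extend handles share offloaded prefixes without interference", {
  buf <- bt_buffer()
  base <- bt_handle()
  prefix <- sample(c("X", "I", "D"), 20, replace = TRUE)
  for (op in prefix) base <- bt_push_op(base, op, buf)
  # two diagonals inherit from the same winner with different ops
  h1 <- bt_push_op(base, "X", buf)
  h2 <- bt_push_op(base, "I", buf)
  # interleave further growth on both chains
  for (i in 1:20) {
    h1 <- bt_push_op(h1, "D", buf)
    h2 <- bt_push_op(h2, "X", buf)
  }
  expect_identical(bt_traceback(buf, h1), c(prefix, "X", rep("D", 20)))
  expect_identical(bt_traceback(buf, h2), c(prefix, "I", rep("X", 20)))
  expect_identical(bt_traceback(buf, base), prefix)  # original untouched
})

test_that("buffer capacity exhaustion is a typed overflow", {
  buf <- bt_buffer(capacity = 1)
  h <- bt_handle()
  for (i in 1:32) h <- bt_push_op(h, "X", buf)  # one offload: at capacity
  expect_identical(bt_buffer_size(buf), 1)
  expect_error(bt_push_op(h, "X", buf), class = "wfa_bt_overflow")
})

test_that("CIGAR reconstruction re-fills match runs around the edit ops", {
  expect_identical(reconstruct_cigar(character(0), "AAAAA", "AAAAA"), "5M")
  expect_identical(reconstruct_cigar("X", "GATTACA", "GACTACA"), "2M1X4M")
  cig <- reconstruct_cigar("I", "AAAA", "AAAAA")
  ops <- cigar_ops(cig)
  expect_identical(sum(ops$len[ops$op == "M"]), 4L)
  expect_identical(sum(ops$len[ops$op == "I"]), 1L)
  # a 3-gap is three consecutive codes forming one run
  cig <- reconstruct_cigar(c("D", "D", "D"), "TAAAG", "TG")
  expect_identical(cig, "1M3D1M")
  # inconsistent scripts are an explicit corruption error
  expect_error(reconstruct_cigar("X", "AAAA", "AAAA"), "inconsistent")
  expect_error(reconstruct_cigar(c("I", "I"), "AA", "AAA"), "inconsistent")
  expect_error(reconstruct_cigar(character(0), "AC", "GT"), "exactly")
})

test_that("reconstructed CIGARs re-score to the engine score across the oracle suite", {
  set.seed(909)
  for (r in 1:100) {
    p <- penalty_grid[[(r %% 4) + 1]]
    pr <- simulate_pairs(1, sample(2:100, 1), runif(1, 0, 0.3))
    a <- wfa_align(pr$query, pr$text, p)
    expect_identical(cigar_score(a$cigar, p), a$score)
    expect_cigar_consumes(a$cigar, pr$query, pr$text)
  }
})

test_that("storage audit reports the succinct-encoding arithmetic", {
  audit <- storage_audit()
  expect_identical(audit$ops_per_block, 16L)
  expect_identical(audit$bits_per_entry, 4)       # (32 + 32) bits / 16 entries
  expect_identical(audit$raw_bits_per_entry, 32L)
  expect_identical(audit$reduction, 8)            # vs 4-byte raw offsets
})

test_that("per-run storage stays within the 12(s+1)^2-byte raw bound", {
  set.seed(111)
  pr <- simulate_pairs(1, 500, 0.08)
  a <- wfa_align(pr$query, pr$text)
  audit <- storage_audit(a)
  expect_lte(audit$run$offsets_allocated, audit$run$offsets_bound)
  expect_identical(audit$run$bytes_raw_bound,
                   12 * (audit$run$score + 1)^2)
  expect_lt(audit$run$bytes_succinct, audit$run$bytes_raw_bound)
})
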