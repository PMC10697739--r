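test_that("hand-checkable alignments produce the expected score and structure", {
  p <- wfa_penalties(4, 6, 2)

  a <- wfa_align("ACGT", "ACGT", p)
  expect_identical(a$score, 0L)
  expect_identical(a$cigar, "4M")
  expect_identical(a$status, "exact")

  # forced single length-1 gap: cost o + e = 8, first non-trivial wavefront
  # is the one at that score (wavefronts s = 0..8 computed)
  a <- wfa_align("AAAA", "AAAAA", p)
  expect_identical(a$score, 8L)
  ops <- cigar_ops(a$cigar)
  expect_identical(sum(ops$len[ops$op == "M"]), 4L)
  expect_identical(sum(ops$len[ops$op %in% c("I", "D")]), 1L)
  expect_identical(a$stats$wavefronts, 9)

  # single mismatch at cost x
  a <- wfa_align("GATTACA", "GACTACA", p)
  expect_identical(a$score, 4L)
  expect_identical(cigar_score(a$cigar, p), 4L)
  expect_cigar_consumes(a$cigar, "GATTACA", "GACTACA")

  # empty sequences short-circuit to the closed-form gap cost
  expect_identical(wfa_align("", "ACGTA", p)$score, 6L + 5L * 2L)
  expect_identical(wfa_align("ACG", "", p)$cigar, "3D")
  expect_identical(wfa_align("", "", p)$score, 0L)
})

test_that("exact scores and CIGARs agree with the full-DP oracle on random instances", {
  set.seed(303)
  for (r in 1:250) {
    p <- penalty_grid[[(r %% 4) + 1]]
    len <- sample(1:120, 1)
    pr <- simulate_pairs(1, len, runif(1, 0, 0.25))
    a <- wfa_align(pr$query, pr$text, p)
    o <- gotoh_align(pr$query, pr$text, p)
    expect_identical(a$score, o$score)
    expect_identical(cigar_score(a$cigar, p), a$score)
    expect_cigar_consumes(a$cigar, pr$query, pr$text)
  }
})

test_that("score is symmetric with insertion/deletion roles swapped", {
  set.seed(404)
  for (r in 1:40) {
    p <- penalty_grid[[(r %% 4) + 1]]
    pr <- simulate_pairs(1, sample(5:80, 1), 0.15)
    a <- wfa_align(pr$query, pr$text, p)
    b <- wfa_align(pr$text, pr$query, p)
    expect_identical(a$score, b$score)
    oa <- cigar_ops(a$cigar); ob <- cigar_ops(b$cigar)
    expect_identical(sum(oa$len[oa$op == "I"]) + sum(oa$len[oa$op == "D"]),
                     sum(ob$len[ob$op == "I"]) + sum(ob$len[ob$op == "D"]))
  }
})

test_that("score never exceeds the injected-edit cost bound", {
  set.seed(505)
  for (r in 1:40) {
    p <- penalty_grid[[(r %% 4) + 1]]
    len <- sample(20:150, 1)
    rate <- runif(1, 0, 0.2)
    pr <- simulate_pairs(1, len, rate)
    k <- pr$edits
    n <- nchar(pr$query); m <- nchar(pr$text)
    bound <- k * max(p$x, p$o + p$e) + abs(n - m) * p$e + (n != m) * p$o
    expect_lte(wfa_distance(pr$query, pr$text, p)$score, bound)
  }
})

test_that("wavefront width and allocated offsets respect the analytic bounds", {
  set.seed(606)
  for (r in 1:20) {
    pr <- simulate_pairs(1, 200, 0.1)
    a <- wfa_align(pr$query, pr$text)
    s <- a$stats$max_score_reached
    expect_lte(a$stats$max_width, 2 * s + 1)
    expect_lte(a$stats$offsets_allocated, estimate_memory(s)$offsets)
  }
})

test_that("a score budget yields a typed budget-exceeded outcome", {
  a <- wfa_align("GATTACA", "GACTACA", max_score = 3)
  expect_identical(a$status, "budget_exceeded")
  expect_true(is.na(a$score))
  # budget equal to the optimum still succeeds
  expect_identical(wfa_align("GATTACA", "GACTACA", max_score = 4)$score, 4L)
  # identical sequences fit a zero budget
  expect_identical(wfa_align("ACGT", "ACGT", max_score = 0)$score, 0L)
})

test_that("distance mode returns the same score with no backtrace bookkeeping", {
  set.seed(707)
  for (r in 1:20) {
    pr <- simulate_pairs(1, sample(10:100, 1), 0.1)
    full <- wfa_align(pr$query, pr$text)
    dist <- wfa_distance(pr$query, pr$text)
    expect_identical(dist$score, full$score)
    expect_null(dist$cigar)
    expect_identical(dist$stats$bt_ops, 0)
  }
})

test_that("memory estimate follows the 3(s+1)^2 offsets formula", {
  expect_identical(estimate_memory(0), list(offsets = 3, bytes_raw = 12))
  expect_identical(estimate_memory(9), list(offsets = 300, bytes_raw = 1200))
})

test_that("lenient mode aligns ambiguity codes as guaranteed mismatches", {
  a <- wfa_align("ACNGT", "ACNGT", lenient = TRUE)
  expect_identical(a$score, 4L)  # the N/N column can only be a mismatch
  expect_identical(a$cigar, "2M1X2M")
  expect_error(wfa_align("ACNGT", "ACNGT"), "position 3")
})

test_that("penalty and CIGAR helpers behave as documented", {
  p <- wfa_penalties(4, 6, 2)
  expect_identical(gap_cost(p, 3L), 12L)
  expect_identical(gap_cost(p, 1:2), c(8L, 10L))
  expect_error(wfa_penalties(0, 6, 2), "x")
  expect_error(wfa_penalties(4, -1, 2), "o")
  expect_identical(cigar_samlike("3M1X6M1D1M"), "10M1D1M")
  expect_identical(cigar_samlike(""), "")
  expect_identical(cigar_score("2M", p), 0L)
  expect_error(cigar_ops("3M4"), "malformed")
})
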