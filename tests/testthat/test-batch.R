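test_that("score budget follows the conservative edit-cost formula", {
  p <- wfa_penalties(4, 6, 2)
  expect_identical(score_budget(100, 100, p, 0.10), 80L)   # 10 edits * max(4, 8)
  expect_identical(score_budget(100, 90, p, 0.10),
                   80L + 6L + 10L * 2L)                    # + one gap of 10
  expect_identical(score_budget(0, 0, p, 0.10), 0L)        # only empty pairs fit
  p2 <- wfa_penalties(5, 2, 4)
  expect_identical(score_budget(50, 50, p2, 0.20), 10L * 6L)  # max(5, 2+4) = 6
  expect_error(score_budget(10, 10, p, 0), "max_error_rate")
})

test_that("pairs within budget are never rescued and all scores stay optimal", {
  set.seed(151)
  pairs <- simulate_pairs(30, 250, 0.05)
  rep <- align_batch(pairs, max_error_rate = 0.10)
  oracle <- mapply(function(q, t) gotoh_align(q, t)$score,
                   pairs$query, pairs$text)
  budgets <- mapply(function(q, t) score_budget(nchar(q), nchar(t)),
                    pairs$query, pairs$text)
  expect_identical(rep$results$score, unname(as.integer(oracle)))
  expect_identical(rep$results$status[oracle <= budgets],
                   rep("exact", sum(oracle <= budgets)))
  expect_identical(rep$counters$total, 30L)
})

test_that("over-budget pairs are rescued by the unbounded exact aligner", {
  set.seed(161)
  ok <- simulate_pairs(12, 200, 0.05)
  noisy <- simulate_pairs(2, 200, 0.30)
  pairs <- rbind(ok, noisy)
  rep <- align_batch(pairs, max_error_rate = 0.10)
  oracle <- mapply(function(q, t) gotoh_align(q, t)$score,
                   pairs$query, pairs$text)
  expect_identical(rep$results$score, unname(as.integer(oracle)))
  expect_identical(rep$results$status[13:14], c("rescued", "rescued"))
  expect_identical(rep$counters$rescued, 2L)
  expect_equal(rep$rescue_fraction, 2 / 14)
})

test_that("degenerate batches are handled cleanly", {
  empty <- align_batch(data.frame(query = character(), text = character()))
  expect_identical(nrow(empty$results), 0L)
  expect_identical(empty$counters$total, 0L)
  expect_identical(empty$rescue_fraction, 0)

  same <- data.frame(query = rep("ACGTACGT", 5), text = rep("ACGTACGT", 5))
  rep <- align_batch(same)
  expect_identical(rep$results$score, rep(0L, 5))
  expect_identical(rep$counters$rescued, 0L)
  expect_identical(rep$results$id, sprintf("pair_%d", 1:5))
})

test_that("raising the assumed error rate never increases the rescued count", {
  set.seed(171)
  pairs <- simulate_pairs(20, 150, runif(1, 0.1, 0.2))
  rescued <- vapply(c(0.02, 0.05, 0.10, 0.25),
                    function(rate) align_batch(pairs, max_error_rate = rate,
                                               distance_only = TRUE)$counters$rescued,
                    integer(1))
  expect_true(all(diff(rescued) <= 0))
})

test_that("results are identical for any worker count", {
  set.seed(181)
  pairs <- simulate_pairs(12, 120, 0.12)
  rep1 <- align_batch(pairs, workers = 1)
  rep2 <- align_batch(pairs, workers = 2, batch_size = 5)
  expect_identical(rep1$results, rep2$results)
  expect_identical(rep1$counters, rep2$counters)
})

test_that("a malformed pair is reported per-pair, not as a batch abort", {
  pairs <- data.frame(query = c("ACGT", "AC-GT", "ACGT"),
                      text = c("ACGT", "ACGT", "ACG"))
  rep <- align_batch(pairs)
  expect_identical(rep$results$status[1], "exact")
  expect_match(rep$results$status[2], "^error")
  expect_true(is.na(rep$results$score[2]))
  expect_identical(rep$results$score[3], gotoh_align("ACGT", "ACG")$score)
  expect_identical(rep$counters$errors, 1L)
})

test_that("approx-mode batches rescue band collapses with exact scores", {
  # length-skewed pair: a narrow static band collapses, rescue recovers it
  pairs <- data.frame(query = c(strrep("A", 10), "ACGTACGT"),
                      text = c(strrep("A", 40), "ACGTACGT"))
  rep <- align_batch(pairs, mode = "approx",
                     band = band_config(beta = 1, lam = 1000),
                     max_error_rate = 1)
  expect_identical(rep$results$status, c("rescued", "approximate"))
  expect_identical(rep$results$score[1], gotoh_align(pairs$query[1], pairs$text[1])$score)
  expect_identical(rep$counters$band_collapsed, 1L)
})
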