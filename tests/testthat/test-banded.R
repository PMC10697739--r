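test_that("most promising diagonal minimises remaining distance to the corner", {
  # single non-NULL diagonal wins outright
  expect_identical(most_promising_diagonal(c(`3` = 5), n = 10, m = 10), 3L)
  # perfect match: diagonal 0 at h = m has remaining distance 0
  expect_identical(most_promising_diagonal(c(`-2` = 5, `0` = 10, `1` = 9),
                                           n = 10, m = 10), 0L)
  # crafted wavefronts vs a brute-force argmin of d(k) = (m-h) + (n-(h-k))
  set.seed(121)
  for (r in 1:50) {
    n <- sample(5:30, 1); m <- sample(5:30, 1)
    ks <- sort(sample((-n):m, sample(2:6, 1)))
    hs <- vapply(ks, function(k) {
      rng <- max(0, k):min(m, n + k)
      if (length(rng) == 1) rng else sample(rng, 1)
    }, numeric(1))
    d <- (m - hs) + (n - (hs - ks))
    got <- most_promising_diagonal(hs, n, m, k = ks)
    expect_identical(d[match(got, ks)], min(d))
  }
  # NA offsets are NULL diagonals; an all-NULL wavefront is a typed collapse
  expect_identical(most_promising_diagonal(c(`-1` = NA, `2` = 4), 5, 5), 2L)
  expect_error(most_promising_diagonal(c(`0` = NA), 5, 5),
               class = "wfa_band_collapse")
})

test_that("ties prefer the target diagonal, then smaller magnitude", {
  # n = 8, m = 10: target diagonal 2; k = 2 and k = 4 tie on d(k)
  expect_identical(most_promising_diagonal(c(`2` = 7, `4` = 8), n = 8, m = 10), 2L)
  # equal distance and equal |k - target|: resolves to the smaller k
  expect_identical(most_promising_diagonal(c(`-1` = 4, `1` = 5), n = 10, m = 10), -1L)
})

test_that("banded alignment is conservative and exact when the band is wide enough", {
  set.seed(131)
  for (r in 1:80) {
    p <- penalty_grid[[(r %% 4) + 1]]
    pr <- simulate_pairs(1, sample(10:120, 1), runif(1, 0, 0.2))
    exact <- wfa_align(pr$query, pr$text, p)
    narrow <- wfa_align(pr$query, pr$text, p,
                        band = band_config(beta = 5, lam = 4))
    if (!is.na(narrow$score)) {
      expect_gte(narrow$score, exact$score)
      expect_identical(narrow$status, "approximate")
      expect_cigar_consumes(narrow$cigar, pr$query, pr$text)
    }
    # an untruncated window (static center, beta >= 2s*+1) recovers the
    # exact score
    beta_full <- 2 * exact$score + 1 + 2 * (exact$score %% 2 == 0)  # odd
    wide <- wfa_align(pr$query, pr$text, p,
                      band = band_config(beta = max(3, beta_full), lam = 100000))
    expect_identical(wide$score, exact$score)
  }
})

test_that("identical sequences align at score 0 under any band", {
  s <- strrep("GATC", 25)
  for (beta in c(1, 3, 129)) {
    b <- wfa_align(s, s, band = band_config(beta = beta, lam = 1))
    expect_identical(b$score, 0L)
  }
})

test_that("a band that can never reach the target collapses with a typed status", {
  b <- wfa_align(strrep("A", 10), strrep("A", 30),
                 band = band_config(beta = 1, lam = 1000))
  expect_identical(b$status, "band_collapse")
  expect_true(is.na(b$score))
  # distinct from the budget outcome
  b2 <- wfa_align(strrep("A", 10), strrep("A", 30), max_score = 2)
  expect_identical(b2$status, "budget_exceeded")
})

test_that("frequent recentering lets a narrow band track a drifting diagonal", {
  q <- strrep("ACGT", 5)
  t <- paste0(strrep("ACGT", 5), strrep("G", 40))  # target diagonal 40
  exact <- wfa_align(q, t)
  tracked <- wfa_align(q, t, band = band_config(beta = 9, lam = 1))
  expect_identical(tracked$score, exact$score)
  # a wide window centered on the target diagonal also covers the path
  targeted <- wfa_align(q, t, band = band_config(beta = 83, lam = 100000,
                                                 center = "target"))
  expect_identical(targeted$score, exact$score)
})

test_that("recall is insensitive to the recentering period", {
  set.seed(141)
  pairs <- simulate_pairs(25, 400, 0.05)
  exact <- mapply(function(q, t) wfa_align(q, t, mode = "distance")$score,
                  pairs$query, pairs$text)
  recall <- vapply(c(10, 50, 100), function(lam) {
    banded <- mapply(function(q, t)
      wfa_align(q, t, mode = "distance",
                band = band_config(beta = 129, lam = lam))$score,
      pairs$query, pairs$text)
    mean(banded == exact)
  }, numeric(1))
  expect_lt(max(recall) - min(recall), 0.01)
})
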