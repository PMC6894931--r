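test_that("connection probability is found over tested", {
  expect_equal(connectionProbability(38, 150), 38 / 150)
  expect_identical(connectionProbability(0, 50), 0)
  expect_identical(connectionProbability(50, 50), 1)
  expect_error(connectionProbability(1, 0), "undefined-proportion")
  expect_error(connectionProbability(5, 4), "found")
})

test_that("Wald interval matches hand arithmetic without correction", {
  w <- waldCiDiff(20, 100, 10, 100, level = 0.90)
  expect_equal(w$diff, 0.10)
  expect_equal(w$se, 0.05)
  expect_equal(w$z, 1.6449, tolerance = 1e-4)
  expect_equal(w$ci, c(0.01775, 0.18225), tolerance = 1e-4)
  # symmetric about zero for equal groups
  s <- waldCiDiff(15, 60, 15, 60)
  expect_equal(s$ci[1], -s$ci[2])
  # the interval always contains the point difference; width shrinks with n
  set.seed(2)
  last_width <- Inf
  for (n in c(50, 500, 5000)) {
    w2 <- waldCiDiff(round(0.2 * n), n, round(0.1 * n), n)
    expect_true(w2$ci[1] <= w2$diff && w2$diff <= w2$ci[2])
    width <- diff(w2$ci)
    expect_lt(width, last_width)
    last_width <- width
  }
})

test_that("Fisher's exact p equals the independent implementation", {
  expect_equal(fisherExact(3, 4, 1, 4), 0.485714285714, tolerance = 1e-9)
  expect_equal(fisherExact(5, 10, 5, 10), 1, tolerance = 1e-12)
  # random tables with margins up to 15 against stats::fisher.test
  set.seed(13)
  for (i in 1:200) {
    n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
    f1 <- sample(0:n1, 1); f2 <- sample(0:n2, 1)
    p <- fisherExact(f1, n1, f2, n2)
    oracle <- stats::fisher.test(matrix(c(f1, n1 - f1, f2, n2 - f2), 2,
                                        byrow = TRUE))$p.value
    expect_equal(p, oracle, tolerance = 1e-9)
    expect_true(p > 0 && p <= 1)
  }
  expect_error(fisherExact(0, 0, 1, 4), "invalid-table")
})

test_that("equivalence verdict follows the TOST/CI duality", {
  x <- c(98, 101, 103, 99, 100, 102, 97, 101)
  eq <- equivalenceReport(x, x, paired = TRUE, bound_pct = 5)
  expect_equal(eq$mean_rel_diff_pct, 0)
  expect_true(eq$equivalent)

  # a true +30% shift is detected as not equivalent at +/-20%
  set.seed(21)
  before <- rnorm(25, 100, 10)
  after <- before * (1.30 + rnorm(25, 0, 0.10))
  ne <- equivalenceReport(before, after, paired = TRUE, bound_pct = 20)
  expect_false(ne$equivalent)
  expect_gt(ne$mean_rel_diff_pct, 20)

  # a small true shift within the bound is declared equivalent at n = 25
  set.seed(22)
  b2 <- rnorm(25, 100, 10)
  a2 <- b2 * (1.05 + rnorm(25, 0, 0.10))
  eq2 <- equivalenceReport(b2, a2, paired = TRUE, bound_pct = 20)
  expect_true(eq2$equivalent)
  expect_lt(abs(eq2$mean_rel_diff_pct - 5), 3 * 10 / sqrt(25))

  # unpaired route: group-mean relative difference with delta-method CI
  set.seed(23)
  g1 <- rnorm(30, 100, 8); g2 <- rnorm(28, 104, 8)
  un <- equivalenceReport(g1, g2, paired = FALSE, bound_pct = 20)
  expect_equal(un$mean_rel_diff_pct, 100 * (mean(g2) - mean(g1)) / mean(g1))
  expect_true(un$ci_pct[1] < un$mean_rel_diff_pct &&
              un$mean_rel_diff_pct < un$ci_pct[2])
  expect_error(equivalenceReport(c(0, 1), c(1, 2), paired = TRUE),
               "zero baseline")
})

test_that("rank tests use exact enumeration for small tie-free samples", {
  # disjoint supports, n = 5 vs 5: exact two-sided p = 2/252
  expect_equal(rankTests(1:5, 11:15), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(rankTests(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)
  # exact and normal approximation agree within 0.02 at n = 10
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10, 0.3)
    p_exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
    expect_equal(rankTests(a, b), p_exact, tolerance = 1e-12)
  }
  expect_error(rankTests(c(1, 1, 1), c(1, 1, 1), paired = TRUE),
               "undefined-test")
  expect_error(rankTests(1:2, 1:5), "at least 3")
})

test_that("distance summaries report per-round median and IQR", {
  one <- distanceSummary(84)
  expect_equal(c(one$median_um, one$q25_um, one$q75_um), c(84, 84, 84))
  three <- distanceSummary(c(60, 84, 110))
  expect_equal(three$median_um, 84)
  # rounds drawn from the same distribution are indistinguishable
  set.seed(41)
  ok <- 0; n_seed <- 50
  for (i in seq_len(n_seed)) {
    d1 <- runif(278, 50, 120); d2 <- runif(278, 50, 120)
    s <- distanceSummary(c(d1, d2), rep(1:2, each = 278))
    expect_equal(s$n, c(278L, 278L))
    if (rankTests(d1, d2) > 0.05) ok <- ok + 1
  }
  expect_gte(ok / n_seed, 0.9)
  expect_warning(distanceSummary(numeric(0), integer(0)), NA)
})

test_that("repeated-measures wrapper returns a valid round-effect p", {
  set.seed(51)
  subj <- rep(1:10, each = 3)
  round <- rep(1:3, 10)
  val <- rnorm(30) + rep(rnorm(10), each = 3)
  p <- repeatedAnova(val, round, subj)
  expect_true(p >= 0 && p <= 1)
})
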