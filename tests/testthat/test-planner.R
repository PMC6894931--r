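test_that("ordered-pair counts match brute-force enumeration", {
  expect_identical(pairsTotal(0), 0L)
  expect_identical(pairsTotal(1), 0L)
  expect_identical(pairsTotal(2), 2L)
  for (n in c(3, 8, 10, 17)) {
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    expect_identical(pairsTotal(n), sum(pairs$i != pairs$j))
  }
  expect_error(pairsTotal(-1), "non-negative")
  expect_error(pairsTotal(2.5), "integer")
})

test_that("extension counts equal enumeration of the merged cluster", {
  # oracle: ordered pairs in the merged set minus old-old pairs already done
  ext_oracle <- function(n_new, n_old) {
    tot <- n_new + n_old
    sum(outer(seq_len(tot), seq_len(tot), "!=")) -
      sum(outer(seq_len(n_old), seq_len(n_old), "!="))
  }
  expect_identical(pairsExtension(0, 5), 0L)
  expect_identical(pairsExtension(4, 4), 44L)
  expect_identical(pairsExtension(5, 3), 50L)
  for (n_new in 0:6) for (n_old in 0:6)
    expect_identical(pairsExtension(n_new, n_old),
                     as.integer(ext_oracle(n_new, n_old)))
  # reduces to the single-cluster formula with nothing maintained
  for (n in 0:50) expect_identical(pairsExtension(n, 0), pairsTotal(n))
  expect_error(pairsExtension(-1, 2), "non-negative")
})

test_that("plan summary accumulates tested pairs without re-marking", {
  plan <- SessionPlan(list(c(8, 0), c(4, 4), c(5, 3)), nPipettes = 8)
  ps <- planSummary(plan)
  expect_identical(ps$total_cells, 17L)
  expect_identical(sum(ps$tested_mask), 150L)
  expect_identical(ps$total_tested, 150L)
  expect_identical(ps$per_session$tested, c(56L, 44L, 50L))

  ps1 <- planSummary(SessionPlan(list(c(8, 0)), nPipettes = 8))
  expect_identical(c(ps1$total_cells, ps1$total_tested), c(8L, 56L))

  ps2 <- planSummary(SessionPlan(list(c(1, 0), c(1, 1)), nPipettes = 2))
  expect_identical(c(ps2$total_cells, ps2$total_tested), c(2L, 2L))
  expect_false(any(diag(ps2$tested_mask)))

  # cell ids are session-qualified, continuing the overall numbering
  expect_identical(rownames(ps$tested_mask)[c(1, 9, 13)],
                   c("1.1", "9.2", "13.3"))
})

test_that("plan invariants are enforced", {
  expect_error(SessionPlan(list(c(4, 1)), nPipettes = 8), "first session")
  expect_error(SessionPlan(list(c(2, 0), c(2, 3)), nPipettes = 8),
               "prior sessions")
  expect_error(SessionPlan(list(c(9, 0)), nPipettes = 8), "n_pipettes")
  expect_error(SessionPlan(list(c(-1, 0)), nPipettes = 8), "non-negative")
})

test_that("plan totals depend only on the session multiset", {
  a <- planSummary(SessionPlan(list(c(6, 0), c(3, 3), c(2, 4)),
                               nPipettes = 6))
  b <- planSummary(SessionPlan(list(c(6, 0), c(2, 4), c(3, 3)),
                               nPipettes = 6))
  expect_identical(a$total_tested, b$total_tested)
  expect_identical(a$total_cells, b$total_cells)
})

test_that("success rate reproduces integer-percent arithmetic", {
  expect_identical(successRate(5.3, 6)$percent, 88L)
  expect_identical(successRate(6.8, 8)$percent, 85L)
  expect_identical(successRate(10, 10)$percent, 100L)
  expect_equal(successRate(5.3, 6)$ratio, 5.3 / 6)
  expect_error(successRate(7, 6), "mean_cells")
  expect_error(successRate(5, 0), "n_pipettes")
})

test_that("yield simulation honours its degenerate limits and seed", {
  y1 <- simulateYield(6, p_patch = 1, p_loss_per_patch = 0, n_rep = 50,
                      seed = 3)
  expect_true(all(y1$cluster_sizes == 6))
  expect_identical(y1$success_rate_pct, 100L)
  y0 <- simulateYield(6, p_patch = 0, n_rep = 50, seed = 3)
  expect_true(all(y0$cluster_sizes == 0))
  expect_true(all(y0$tested_connections == 0))
  again <- simulateYield(8, 0.8, 0.02, cleaning = TRUE, n_rep = 200, seed = 7)
  twice <- simulateYield(8, 0.8, 0.02, cleaning = TRUE, n_rep = 200, seed = 7)
  expect_identical(again$cluster_sizes, twice$cluster_sizes)
})

test_that("yield model matches the exact absorbing-chain oracle", {
  p <- 0.7; q <- 0.1; n_pip <- 3
  for (att in c(1L, 3L)) {    # no cleaning vs cleaning with 2 retries
    dist <- yieldSizeDist(n_pip, p, q, att)
    exact_mean <- sum((0:n_pip) * dist)
    mc <- simulateYield(n_pip, p, q, cleaning = att > 1L, max_retries = att - 1L,
                        n_rep = 4000, seed = 11)
    se <- stats::sd(mc$cluster_sizes) / sqrt(4000)
    expect_lt(abs(mc$mean_cluster_size - exact_mean), 4 * se + 1e-9)
  }
})

test_that("cleaning stochastically dominates no cleaning in cluster size", {
  with_cl <- simulateYield(8, 0.9, 0.01, cleaning = TRUE, max_retries = 2,
                           n_rep = 10000, seed = 1)
  without <- simulateYield(8, 0.9, 0.01, cleaning = FALSE, n_rep = 10000,
                           seed = 1)
  expect_gte(with_cl$mean_cluster_size, without$mean_cluster_size)
  # dominance of the survival function at every size
  for (k in 0:8)
    expect_gte(mean(with_cl$cluster_sizes >= k),
               mean(without$cluster_sizes >= k) - 0.01)
})

test_that("session plans round-trip through JSON", {
  plan <- SessionPlan(list(c(8, 0), c(4, 4)), nPipettes = 8)
  f <- tempfile(fileext = ".json")
  writeSessionPlan(plan, f)
  back <- readSessionPlan(f)
  expect_identical(sessions(back), sessions(plan))
  expect_identical(nPipettes(back), nPipettes(plan))
})
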