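test_that("template-scaling criterion equals the per-offset OLS oracle", {
  set.seed(11)
  y <- rnorm(3000)
  tmpl <- cbTemplate(2, 10, rate = 2000)
  cb <- cbCriterion(y, tmpl)
  expect_identical(length(cb$criterion), 3000L - length(tmpl) + 1L)
  for (off in c(1, 57, 500, 1500, length(cb$criterion))) {
    oracle <- olsCriterionAt(y, tmpl, off)
    expect_equal(cb$scale[off], oracle$scale, tolerance = 1e-9)
    expect_equal(cb$criterion[off], oracle$criterion, tolerance = 1e-9)
  }
})

test_that("criterion is scale-exact and offset-invariant on clean data", {
  tmpl <- cbTemplate(2, 20)
  y <- c(rep(0, 50), 3 * tmpl, rep(0, 50)) + 7     # constant offset
  cb <- cbCriterion(y, tmpl)
  expect_equal(cb$scale[51], 3, tolerance = 1e-9)
  expect_identical(cb$criterion[51], 1e6)          # perfect fit capped
  # shifting data and window together shifts the series (equivariance)
  y2 <- c(rep(7, 30), y)
  cb2 <- cbCriterion(y2, tmpl)
  expect_equal(cb2$scale[81], 3, tolerance = 1e-9)
  expect_equal(cb$criterion[1:50], cb2$criterion[31:80], tolerance = 1e-12)
  expect_error(cbCriterion(tmpl[1:10], tmpl), "shorter")
})

test_that("spontaneous events are recovered with few false calls", {
  sp <- spontTrace(seed = 112)                      # 10 events
  expect_identical(nrow(sp$events), 10L)
  det <- detectSpontEvents(sp$trace)
  m <- matchEvents(sp$events$time_s, det$events$time_s)
  expect_gte(m$recall, 0.9)
  expect_lte(m$fp, 1)
  expect_equal(det$frequency_hz, nrow(det$events) / 2)

  # noise-only trace: no events at the default criterion
  quiet <- spontTrace(rate_hz = 0, noise_sd_mv = 0.15, seed = 30)
  d0 <- detectSpontEvents(quiet$trace)
  expect_identical(nrow(d0$events), 0L)
})

test_that("noiseless unit events yield exact amplitudes and frequency", {
  k <- pspKernel(2, 20)
  x <- rep(-65, 40000)
  for (t0 in c(4000, 16000, 30000)) {
    idx <- t0:(t0 + length(k) - 1)
    x[idx] <- x[idx] + k
  }
  det <- detectSpontEvents(Trace(x))
  expect_identical(nrow(det$events), 3L)
  expect_equal(det$events$amplitude_mv, rep(1, 3), tolerance = 1e-6)
  expect_equal(det$median_amplitude_mv, 1, tolerance = 1e-6)
  expect_equal(det$frequency_hz, 1.5)               # 3 events / 2 s
})

test_that("sweep averaging is the pointwise mean", {
  dat <- array(0, c(100, 1, 4))
  for (s in 1:4) dat[, 1, s] <- s
  ss <- new("SweepSet", data = dat, rate = 20000, protocol = list(),
            seed = 1L, groundTruth = NULL)
  avg <- averageSweeps(ss, 1)
  expect_true(all(traceSamples(avg) == 2.5))
  expect_identical(attr(avg@samples, "n_averaged"), 4L)
  # +v / -v alternating cancels
  dat2 <- array(rep(c(1, -1), each = 100), c(100, 1, 2))
  ss2 <- new("SweepSet", data = dat2, rate = 20000, protocol = list(),
             seed = 1L, groundTruth = NULL)
  expect_true(all(traceSamples(averageSweeps(ss2, 1)) == 0))
})

test_that("connection calls gate on amplitude and monosynaptic latency", {
  fs <- 20000
  flat <- Trace(rep(-60, 30000))
  cc <- callConnection(flat, spike_times_s = 0.5)
  expect_false(cc$connected)
  expect_equal(cc$amplitude_mv, 0)

  # a clean evoked PSP: connected, amplitude and latency near truth
  k <- pspKernel(2, 20)
  x <- rep(-60, 30000)
  spike <- 0.5; lat_ms <- 1.5; amp <- 0.5
  i0 <- round((spike + lat_ms / 1000) * fs) + 1
  x[i0:(i0 + length(k) - 1)] <- x[i0:(i0 + length(k) - 1)] + amp * k
  set.seed(8)
  xn <- x + rnorm(length(x), 0, 0.05 / sqrt(1))   # averaged-trace-like noise
  tr <- Trace(xn)
  cc2 <- callConnection(tr, spike_times_s = spike, k_sd = 3)
  expect_true(cc2$connected)
  expect_lt(abs(cc2$amplitude_mv - amp), 0.05)
  expect_lt(abs(cc2$latency_ms - lat_ms), 0.5)

  # polysynaptic surrogate at 8 ms fails the latency gate
  x8 <- rep(-60, 30000)
  i8 <- round((spike + 0.008) * fs) + 1
  x8[i8:(i8 + length(k) - 1)] <- x8[i8:(i8 + length(k) - 1)] + amp * k
  set.seed(9)
  cc3 <- callConnection(Trace(x8 + rnorm(length(x8), 0, 0.01)),
                        spike_times_s = spike, k_sd = 3)
  expect_false(cc3$connected)
  expect_gt(cc3$latency_ms, 5)

  expect_error(callConnection(Trace(rep(-60, 1200)), spike_times_s = 0.055),
               "response window")
})

test_that("cluster screening recovers ground truth at high SNR", {
  ss <- synthCluster(5, p_conn = 0.25, n_sweeps = 40, seed = 77)
  calls <- detectConnections(ss, k_sd = 10)
  expect_identical(nrow(calls), 20L)                 # n(n-1) ordered pairs
  called <- matrix(FALSE, 5, 5)
  called[cbind(calls$pre, calls$post)] <- calls$connected
  expect_identical(called, adjacency(groundTruth(ss)))
})

test_that("connectivity assembly checks coverage and reconciles totals", {
  plan <- SessionPlan(list(c(8, 0), c(4, 4), c(5, 3)), nPipettes = 8)
  ps <- planSummary(plan)
  idx <- which(ps$tested_mask, arr.ind = TRUE)
  ids <- rownames(ps$tested_mask)
  calls <- data.frame(pre_id = ids[idx[, 1]], post_id = ids[idx[, 2]],
                      connected = FALSE, amplitude_mV = 0, latency_ms = NA)
  calls$connected[1:38] <- TRUE
  res <- buildConnectivity(calls, plan)
  expect_identical(sum(testedMask(res)), 150L)
  expect_identical(sum(connectedMask(res)), 38L)
  expect_true(all(testedMask(res)[connectedMask(res)]))  # connected within tested
  expect_error(buildConnectivity(calls[-1, ], plan), "coverage-mismatch")
  expect_error(buildConnectivity(calls[-1, ], plan), calls$pre_id[1],
               fixed = TRUE)
  extra <- rbind(calls, data.frame(pre_id = "1.1", post_id = "1.1",
                                   connected = FALSE, amplitude_mV = 0,
                                   latency_ms = NA))
  expect_error(buildConnectivity(extra, plan), "coverage-mismatch")
})
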