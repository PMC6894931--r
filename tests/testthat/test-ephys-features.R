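test_that("resting potential averages the leading baseline", {
  tr <- Trace(rep(-65, 4000))
  expect_identical(restingPotential(tr), -65)
  set.seed(3)
  noisy <- Trace(-65 + rnorm(4000, 0, 0.2))
  expect_lt(abs(restingPotential(noisy) + 65), 3 * 0.2 / sqrt(2000))
  expect_error(restingPotential(Trace(rep(-65, 100))), "exceeds")
  expect_error(restingPotential(Trace(rep(0, 4000), clampMode = "voltage")),
               "current-clamp")
})

test_that("passive properties are recovered from noiseless test pulses", {
  for (ra in c(5, 15, 30)) for (rin in c(50, 150, 300))
    for (cm in c(50, 120, 200)) {
      tp <- vcTestPulse(cellParams(ra_mohm = ra, rin_mohm = rin, cm_pf = cm))
      m <- measureResistances(tp$trace, onset_s = tp$onset_s,
                              width_s = tp$width_s)
      expect_lt(abs(m$ra_mohm - ra) / ra, 0.05)
      expect_lt(abs(m$rin_mohm - rin) / rin, 0.02)
    }
})

test_that("degenerate pulse responses are flagged", {
  fs <- 20000
  # pure resistor: no capacitive transient, peak equals steady state
  flat <- Trace(c(rep(0, 1000), rep(100, 4000), rep(0, 1000)),
                clampMode = "voltage")
  m <- measureResistances(flat, onset_s = 1000 / fs, width_s = 4000 / fs)
  expect_identical(m$flag, "rin-infinite")
  expect_identical(m$rin_mohm, Inf)
  expect_equal(m$ra_mohm, 100)
  # non-physical: steady state below baseline
  neg <- Trace(c(rep(0, 1000), rep(-50, 4000), rep(0, 1000)),
               clampMode = "voltage")
  m2 <- measureResistances(neg, onset_s = 1000 / fs, width_s = 4000 / fs)
  expect_identical(m2$flag, "non-physical")
  expect_true(is.na(m2$ra_mohm))
})

test_that("spike detection finds the train and rejects subthreshold traces", {
  tr <- apTrain()
  spk <- detectSpikes(tr$trace)
  expect_identical(length(spk), 4L)
  true_idx <- round(tr$spike_times_s * 20000) + 1
  expect_true(all(abs(spk - true_idx) <= 1))
  expect_identical(length(detectSpikes(Trace(rep(-65, 2000)))), 0L)
  # subthreshold PSPs peak below 0 mV
  sp <- spontTrace(rate_hz = 5, noise_sd_mv = 0.1, seed = 2)
  expect_identical(length(detectSpikes(sp$trace)), 0L)
})

test_that("AP features recover the generator's analytic ground truth", {
  fs <- 20000
  tr <- apTrain()
  spk <- detectSpikes(tr$trace)
  f <- apFeatures(tr$trace, spk[2])
  expect_equal(f$amplitude_mv, f$peak_mv - f$threshold_mv)   # identity
  gt_thr_idx <- round(tr$threshold_times_s[2] * fs) + 1
  expect_lte(abs(f$threshold_idx - gt_thr_idx), 1)
  # voltage tolerance: the local per-sample step at the crossing
  x <- traceSamples(tr$trace)
  vstep <- max(abs(diff(x[(gt_thr_idx - 2):(gt_thr_idx + 2)])))
  expect_lt(abs(f$threshold_mv - tr$threshold_mv), vstep + 1e-9)
  expect_lt(abs(f$half_width_ms - tr$halfwidth_ms), 1000 / fs)
  expect_gt(f$max_depol_rate, 0)
  expect_lt(f$max_repol_rate, 0)
})

test_that("half-width of a symmetric triangular spike is the closed form", {
  fs <- 20000
  up <- seq(-60, 20, by = 25 / 20)          # 25 mV/ms rise at 20 kHz
  wave <- c(rep(-60, 200), up, rev(up)[-1], rep(-60, 200))
  tr <- Trace(wave)
  spk <- detectSpikes(tr)
  f <- apFeatures(tr, spk[1])
  # triangle: time above half-amplitude = amplitude / slope
  expect_equal(f$half_width_ms, f$amplitude_mv / 25, tolerance = 0.06)
})

test_that("rheobase selection returns the second-lowest spiking amplitude", {
  amps <- seq(0.5, 4, by = 0.5)
  g1 <- data.frame(amplitude_na = amps, duration_ms = 1,
                   spiked = amps >= 2)
  expect_identical(selectRheobaseStimulus(g1),
                   list(amplitude_na = 2.5, duration_ms = 1))
  g2 <- data.frame(amplitude_na = amps, duration_ms = 1,
                   spiked = amps >= 4)
  expect_identical(selectRheobaseStimulus(g2),
                   list(amplitude_na = 4, duration_ms = 1))     # capped
  g3 <- rbind(data.frame(amplitude_na = amps, duration_ms = 1, spiked = FALSE),
              data.frame(amplitude_na = amps, duration_ms = 2,
                         spiked = amps >= 1.5))
  expect_identical(selectRheobaseStimulus(g3),
                   list(amplitude_na = 2, duration_ms = 2))
  g4 <- data.frame(amplitude_na = amps, duration_ms = 1, spiked = FALSE)
  expect_error(selectRheobaseStimulus(g4), "stimulus-not-found")
})

test_that("QC filter applies the verbatim boundary semantics", {
  cells <- data.frame(
    cell_id = paste0("c", 1:5),
    rmp_mV = c(-65, -58, -70, -61, -60),
    ra_MOhm = c(20, 20, 129, 39, 40))
  qc <- qcFilter(cells)
  expect_identical(sum(qc$included), 2L)       # c1 and c4
  expect_true(all(qc$included[c(1, 4)]))
  expect_identical(qc$exclusion_reason[2], "rmp_above_cutoff")
  expect_identical(qc$exclusion_reason[3], "high_access_resistance")
  expect_identical(qc$exclusion_reason[5], "high_access_resistance")  # Ra=40
  expect_true(all(!qc$included | is.na(qc$exclusion_reason)))
  # idempotent and order-independent
  again <- qcFilter(qc)
  expect_identical(again$included, qc$included)
  shuf <- qcFilter(cells[c(3, 1, 5, 2, 4), ])
  expect_identical(shuf$included[match(cells$cell_id, shuf$cell_id)],
                   qc$included)
  expect_error(qcFilter(data.frame(x = 1)), "invalid-table")
})
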