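#' Default cell parameters for the synthetic generator
#'
#' Conventional cortical pyramidal-cell values: resting potential, access
#' and input resistance, capacitance, a holding potential near -60 mV
#' (maintained by constant current injection), the rheobase of the
#' stereotyped spike generator and the action-potential shape parameters
#' (see \code{\link{apShape}}).
#'
#' @param rmp_mv resting membrane potential (mV).
#' @param ra_mohm access (series) resistance (MOhm).
#' @param rin_mohm input resistance (MOhm).
#' @param cm_pf membrane capacitance (pF).
#' @param holding_mv holding potential in current clamp (mV).
#' @param rheobase_na minimal stimulus amplitude that elicits a spike (nA).
#' @param ... overrides for AP shape parameters (\code{ramp_slope},
#'   \code{v0_mv}, \code{tau_rise_ms}, \code{peak_mv}, \code{ahp_mv},
#'   \code{tau_fall_ms}, \code{tau_ahp_ms}).
#' @return named list of parameters.
#' @export
cellParams <- function(rmp_mv = -65, ra_mohm = 15, rin_mohm = 100,
                       cm_pf = 100, holding_mv = -62, rheobase_na = 1,
                       ...) {
  stopifnot(ra_mohm > 0, rin_mohm > 0, cm_pf > 0)
  p <- list(rmp_mv = rmp_mv, ra_mohm = ra_mohm, rin_mohm = rin_mohm,
            cm_pf = cm_pf, holding_mv = holding_mv,
            rheobase_na = rheobase_na,
            ramp_slope = 5, v0_mv = -50, tau_rise_ms = 0.15,
            peak_mv = 25, ahp_mv = 4, tau_fall_ms = 0.8, tau_ahp_ms = 8)
  dots <- list(...)
  p[names(dots)] <- dots
  if (p$v0_mv + 10 * p$tau_rise_ms - p$ramp_slope * p$tau_rise_ms >= p$peak_mv)
    stop("threshold must lie below peak", call. = FALSE)
  p
}

#' Unit-peak postsynaptic-potential kernel (difference of exponentials)
#'
#' k(t) = N (exp(-t/decay) - exp(-t/rise)) normalised to a peak of exactly 1
#' at the sampled maximum. The analytic peak time
#' log(decay/rise) * rise * decay / (decay - rise) is attached as attribute
#' \code{peak_time_ms}; the kernel spans ten decay constants.
#'
#' @param rise_ms,decay_ms kinetics in ms, 0 < rise < decay.
#' @param rate sampling rate, Hz.
#' @return numeric kernel vector with attribute \code{peak_time_ms}.
#' @examples
#' k <- pspKernel(2, 20)
#' attr(k, "peak_time_ms")   # ~5.117
#' max(k)                    # exactly 1
#' @export
pspKernel <- function(rise_ms, decay_ms, rate = 20000) {
  if (!(rise_ms > 0 && decay_ms > rise_ms))
    stop("invalid-kinetics: need 0 < rise < decay", call. = FALSE)
  t_ms <- seq(0, 10 * decay_ms, by = 1000 / rate)
  k <- exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms)
  k <- k / max(k)
  attr(k, "peak_time_ms") <-
    log(decay_ms / rise_ms) * rise_ms * decay_ms / (decay_ms - rise_ms)
  k
}

#' Stereotyped action-potential waveform with analytic ground truth
#'
#' Piecewise waveform added on top of the holding potential: a linear
#' stimulus-driven ramp from holding to \code{v0_mv} at \code{ramp_slope}
#' mV/ms, a regenerative exponential rise (slope-continuous at v0) to
#' \code{peak_mv}, an exponential repolarisation to an afterhyperpolarisation
#' \code{ahp_mv} below holding, and a slow recovery. The construction makes
#' the 10 mV/ms threshold crossing, the peak and the half-width all
#' closed-form.
#'
#' @param params from \code{\link{cellParams}}.
#' @param rate sampling rate, Hz.
#' @return list: \code{wave} (mV relative to holding, starting at stimulus
#'   onset), and analytic ground truth \code{threshold_ms},
#'   \code{threshold_mv} (absolute, given holding), \code{peak_ms},
#'   \code{peak_mv}, \code{halfwidth_ms} — times relative to stimulus onset.
#' @export
apShape <- function(params = cellParams(), rate = 20000) {
  dt <- 1000 / rate
  hold <- params$holding_mv
  s0 <- params$ramp_slope; v0 <- params$v0_mv - hold   # relative to holding
  tr <- params$tau_rise_ms; tf <- params$tau_fall_ms
  vp <- params$peak_mv - hold
  vahp <- -params$ahp_mv
  c0 <- s0 * tr                                # slope-continuity constant
  d0 <- v0 / s0                                # ramp duration, ms
  t_pk <- d0 + tr * log(1 + (vp - v0) / c0)
  d_f <- 6 * tf
  v_sw <- vahp + (vp - vahp) * exp(-6)
  d_ahp <- 6 * params$tau_ahp_ms
  t_end <- t_pk + d_f + d_ahp
  t <- seq(0, t_end, by = dt)
  w <- numeric(length(t))
  a <- t <= d0
  w[a] <- s0 * t[a]
  b <- t > d0 & t <= t_pk
  w[b] <- v0 + c0 * (exp((t[b] - d0) / tr) - 1)
  cidx <- t > t_pk & t <= t_pk + d_f
  w[cidx] <- vahp + (vp - vahp) * exp(-(t[cidx] - t_pk) / tf)
  d <- t > t_pk + d_f
  w[d] <- v_sw * exp(-(t[d] - t_pk - d_f) / params$tau_ahp_ms)
  thr_ms <- d0 + tr * log(10 / s0)
  thr_mv <- hold + v0 + 10 * tr - c0
  v_half <- (thr_mv - hold + vp) / 2           # midpoint threshold..peak
  t_up <- d0 + tr * log(1 + (v_half - v0) / c0)
  t_dn <- t_pk + tf * log((vp - vahp) / (v_half - vahp))
  list(wave = w,
       threshold_ms = thr_ms, threshold_mv = thr_mv,
       peak_ms = t_pk, peak_mv = params$peak_mv,
       halfwidth_ms = t_dn - t_up)
}

# 4th-order Butterworth low-pass, applied single-pass (used on the additive
# noise component only, so the deterministic signal keeps its analytic
# ground truth).
.lowpassNoise <- function(x, rate, cutoff_hz = 6000) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate / 2) return(x)
  bf <- signal::butter(4, 2 * cutoff_hz / rate, type = "low")
  sdx <- stats::sd(x)
  y <- as.numeric(signal::filter(bf, x))
  # renormalise so the stated noise SD is the SD of the delivered noise
  if (sdx > 0) y <- y * (sdx / stats::sd(y))
  y
}

# column-wise Butterworth low-pass of a noise matrix via stats::filter
# (FIR numerator then recursive denominator), renormalised per column so
# every column's delivered SD equals sd_target
.lowpassMatrix <- function(x, rate, cutoff_hz = 6000, sd_target = NULL) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate / 2) return(x)
  bf <- signal::butter(4, 2 * cutoff_hz / rate, type = "low")
  y <- stats::filter(x, bf$b, method = "convolution", sides = 1)
  y[is.na(y)] <- 0                               # leading edge
  y <- stats::filter(y, -bf$a[-1L], method = "recursive")
  y <- matrix(as.numeric(y), nrow(x), ncol(x))
  if (!is.null(sd_target)) {
    sds <- sqrt(colMeans(y^2) - colMeans(y)^2)
    y <- sweep(y, 2L, ifelse(sds > 0, sd_target / sds, 1), `*`)
  }
  y
}

#' Voltage-clamp membrane test pulse with known passive properties
#'
#' Single-compartment response to a square voltage step dV:
#' I(t) = dV/Ra exp(-t/tau) + dV/(Ra+Rin) (1 - exp(-t/tau)),
#' tau = Cm Ra Rin / (Ra + Rin), in pA with baseline segments before and
#' after the pulse. Gaussian noise is added (and 6 kHz low-passed) when
#' \code{noise_sd_pa > 0}.
#'
#' @param params from \code{\link{cellParams}}.
#' @param dv_mv step amplitude, mV (default 10).
#' @param width_ms pulse width, ms (default 200).
#' @param baseline_ms pre/post baseline, ms.
#' @param noise_sd_pa noise SD, pA.
#' @param rate sampling rate, Hz.
#' @param seed integer seed (only used when noise is added).
#' @return list: \code{trace} (\linkS4class{Trace}, voltage clamp),
#'   \code{onset_s}, \code{width_s}, \code{tau_ms}, \code{peak_pa},
#'   \code{ss_pa}.
#' @examples
#' tp <- vcTestPulse(cellParams(ra_mohm = 10, rin_mohm = 90, cm_pf = 100))
#' tp$tau_ms          # 0.9
#' tp$peak_pa         # 1000
#' @export
vcTestPulse <- function(params = cellParams(), dv_mv = 10, width_ms = 200,
                        baseline_ms = 50, noise_sd_pa = 0, rate = 20000,
                        seed = 1L) {
  ra <- params$ra_mohm; rin <- params$rin_mohm; cm <- params$cm_pf
  tau_ms <- cm * (ra * rin) / (ra + rin) / 1000   # pF*MOhm = us
  n_base <- round(baseline_ms / 1000 * rate)
  n_pulse <- round(width_ms / 1000 * rate)
  t_ms <- (seq_len(n_pulse) - 1L) / rate * 1000
  peak <- 1000 * dv_mv / ra                        # pA
  ss <- 1000 * dv_mv / (ra + rin)
  pulse <- peak * exp(-t_ms / tau_ms) + ss * (1 - exp(-t_ms / tau_ms))
  i <- c(rep(0, n_base), pulse, rep(0, n_base))
  if (noise_sd_pa > 0) {
    old <- .childRNG(seed, "vcpulse")
    i <- i + .lowpassNoise(stats::rnorm(length(i), 0, noise_sd_pa), rate)
    .restoreRNG(old)
  }
  list(trace = Trace(i, rate = rate, clampMode = "voltage"),
       onset_s = n_base / rate, width_s = n_pulse / rate,
       tau_ms = tau_ms, peak_pa = peak, ss_pa = ss)
}

#' Current-clamp action-potential train for one stimulation slot
#'
#' One stereotyped AP (see \code{\link{apShape}}) per suprathreshold pulse;
#' subthreshold stimuli produce passive bumps and no spikes. Ground-truth
#' spike times and the analytic threshold crossing are returned.
#'
#' @param params from \code{\link{cellParams}}.
#' @param n_pulses pulses in the slot (default 4).
#' @param pulse_rate_hz within-slot rate (default 20).
#' @param amplitude_na,width_ms stimulus amplitude (nA) and width (ms).
#' @param onset_s time of the first pulse within the trace.
#' @param duration_s trace duration.
#' @param noise_sd_mv additive noise SD (mV), 6 kHz low-passed.
#' @param rate sampling rate, Hz.
#' @param seed integer seed.
#' @return list: \code{trace}, \code{spike_times_s} (peak times),
#'   \code{threshold_times_s}, \code{threshold_mv}, \code{halfwidth_ms},
#'   \code{peak_mv}, \code{stim_times_s}.
#' @export
apTrain <- function(params = cellParams(), n_pulses = 4L, pulse_rate_hz = 20,
                    amplitude_na = 2, width_ms = 2, onset_s = 0.1,
                    duration_s = 0.5, noise_sd_mv = 0, rate = 20000,
                    seed = 1L) {
  stopifnot(amplitude_na >= 0, width_ms > 0)
  n <- round(duration_s * rate)
  v <- rep(params$holding_mv, n)
  stim_times <- onset_s + (seq_len(n_pulses) - 1L) / pulse_rate_hz
  shp <- apShape(params, rate)
  spikes <- numeric(0); thr_times <- numeric(0)
  if (amplitude_na >= params$rheobase_na) {
    for (st in stim_times) {
      i0 <- round(st * rate) + 1L
      idx <- i0:min(n, i0 + length(shp$wave) - 1L)
      v[idx] <- v[idx] + shp$wave[seq_along(idx)]
      spikes <- c(spikes, st + shp$peak_ms / 1000)
      thr_times <- c(thr_times, st + shp$threshold_ms / 1000)
    }
  } else if (amplitude_na > 0) {
    # passive depolarising bump, well below 0 mV
    bump <- pspKernel(1, 10, rate) * amplitude_na * params$rin_mohm * 0.05
    for (st in stim_times) {
      i0 <- round(st * rate) + 1L
      idx <- i0:min(n, i0 + length(bump) - 1L)
      v[idx] <- v[idx] + bump[seq_along(idx)]
    }
  }
  if (noise_sd_mv > 0) {
    old <- .childRNG(seed, "aptrain")
    v <- v + .lowpassNoise(stats::rnorm(n, 0, noise_sd_mv), rate)
    .restoreRNG(old)
  }
  list(trace = Trace(v, rate = rate, clampMode = "current"),
       spike_times_s = spikes, threshold_times_s = thr_times,
       threshold_mv = shp$threshold_mv, halfwidth_ms = shp$halfwidth_ms,
       peak_mv = shp$peak_mv, stim_times_s = stim_times)
}

#' Resting trace with spontaneous EPSPs
#'
#' Homogeneous-Poisson event times over the trace, each adding a scaled
#' \code{\link{pspKernel}}; Gaussian 6 kHz-low-passed baseline noise. Event
#' amplitudes are log-normal with the requested mean and SD.
#'
#' @param rate_hz event rate (events/s).
#' @param amp_mean_mv,amp_sd_mv amplitude distribution (mV).
#' @param rise_ms,decay_ms PSP kinetics.
#' @param duration_s trace duration (default 2, at resting potential).
#' @param noise_sd_mv baseline noise SD (mV).
#' @param rmp_mv resting potential (mV).
#' @param rate sampling rate, Hz.
#' @param seed integer seed.
#' @return list: \code{trace}, \code{events} data.frame
#'   (\code{time_s}, \code{amplitude_mv}).
#' @export
spontTrace <- function(rate_hz = 5, amp_mean_mv = 0.9, amp_sd_mv = 0.15,
                       rise_ms = 2, decay_ms = 20, duration_s = 2,
                       noise_sd_mv = 0.15, rmp_mv = -65, rate = 20000,
                       seed = 1L) {
  stopifnot(rate_hz >= 0)
  old <- .childRNG(seed, "spont")
  on.exit(.restoreRNG(old))
  n <- round(duration_s * rate)
  n_ev <- stats::rpois(1L, rate_hz * duration_s)
  times <- sort(stats::runif(n_ev, 0, duration_s))
  amps <- if (n_ev > 0) .rlnormMeanSd(n_ev, amp_mean_mv, amp_sd_mv)
          else numeric(0)
  v <- rep(rmp_mv, n)
  if (n_ev > 0) {
    k <- pspKernel(rise_ms, decay_ms, rate)
    for (e in seq_len(n_ev)) {
      i0 <- round(times[e] * rate) + 1L
      idx <- i0:min(n, i0 + length(k) - 1L)
      v[idx] <- v[idx] + amps[e] * k[seq_along(idx)]
    }
  }
  if (noise_sd_mv > 0)
    v <- v + .lowpassNoise(stats::rnorm(n, 0, noise_sd_mv), rate)
  list(trace = Trace(v, rate = rate, clampMode = "current"),
       events = data.frame(time_s = times, amplitude_mv = amps))
}

# log-normal draws parameterised by arithmetic mean and SD
.rlnormMeanSd <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  sig2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
}

#' Synthetic multipatch connectivity-screening cluster
#'
#' Generates a full sweep set for a simultaneously recorded cluster: each
#' cell receives a stimulation slot of \code{n_pulses} action potentials at
#' \code{pulse_rate_hz} (slots separated by a quiet gap), directed
#' connectivity is drawn Erdos-Renyi at \code{p_conn}, and every presynaptic
#' spike adds a latency-shifted, trial-jittered PSP to each connected
#' postsynaptic channel. Cells are held near -60 mV; noise is white Gaussian
#' low-passed at 6 kHz. Output is bit-reproducible for a fixed seed.
#'
#' @param n_cells cluster size (>= 2).
#' @param p_conn directed connection probability.
#' @param n_sweeps sweeps (30-50 typical; default 40).
#' @param amp_mean_mv,amp_sd_mv,amp_min_mv unitary PSP amplitude
#'   distribution (log-normal, truncated below at \code{amp_min_mv}).
#' @param latency_mean_ms,latency_sd_ms synaptic latency distribution
#'   (truncated to [0.8, 4] ms, monosynaptic).
#' @param rise_ms,decay_ms PSP kinetics.
#' @param trial_cv trial-to-trial amplitude coefficient of variation
#'   (multiplicative log-normal).
#' @param noise_sd_mv per-sweep noise SD (mV).
#' @param gap_s quiet gap between stimulation slots (s, default 0.25).
#' @param params cell parameters (\code{\link{cellParams}}).
#' @param rate sampling rate, Hz.
#' @param seed integer root seed.
#' @return a \linkS4class{SweepSet} carrying a
#'   \linkS4class{GroundTruthNetwork}.
#' @examples
#' ss <- synthCluster(3, p_conn = 0.5, n_sweeps = 5, seed = 42)
#' ss
#' @export
synthCluster <- function(n_cells, p_conn = 0.15, n_sweeps = 40L,
                         amp_mean_mv = 0.5, amp_sd_mv = 0.2,
                         amp_min_mv = 0.2, latency_mean_ms = 1.5,
                         latency_sd_ms = 0.3, rise_ms = 2, decay_ms = 20,
                         trial_cv = 0.3, noise_sd_mv = 0.2, gap_s = 0.25,
                         params = cellParams(), rate = 20000, seed = 1L) {
  if (n_cells < 2L) stop("n_cells must be at least 2", call. = FALSE)
  stopifnot(p_conn >= 0, p_conn <= 1, n_sweeps >= 1)
  old <- .childRNG(seed, "cluster")
  on.exit(.restoreRNG(old))

  n_pulses <- 4L; pulse_rate <- 20
  slot_len <- (n_pulses - 1L) / pulse_rate + 0.05   # last AP + 50 ms tail
  first_onset <- 0.1
  slot_onsets <- first_onset + (seq_len(n_cells) - 1L) * (slot_len + gap_s)
  dur <- slot_onsets[n_cells] + slot_len + 0.05
  n <- round(dur * rate)

  # ground truth
  A <- matrix(stats::runif(n_cells^2) < p_conn, n_cells, n_cells)
  diag(A) <- FALSE
  amp <- matrix(0, n_cells, n_cells)
  lat <- matrix(0, n_cells, n_cells)
  ne <- sum(A)
  if (ne > 0) {
    amp[A] <- pmax(.rlnormMeanSd(ne, amp_mean_mv, amp_sd_mv), amp_min_mv)
    lat[A] <- pmin(pmax(stats::rnorm(ne, latency_mean_ms, latency_sd_ms),
                        0.8), 4)
  }
  theta <- stats::runif(n_cells, 0, 2 * pi)
  rr <- 100 * sqrt(stats::runif(n_cells))
  pos <- cbind(rr * cos(theta), rr * sin(theta), stats::runif(n_cells, -20, 20))
  gt <- new("GroundTruthNetwork", adjacency = A, amplitude = amp,
            latency = lat,
            rise = matrix(rise_ms, n_cells, n_cells),
            decay = matrix(decay_ms, n_cells, n_cells),
            trialCV = trial_cv, positions = pos)

  # deterministic signal: holding + per-cell AP trains (identical each sweep)
  shp <- apShape(params, rate)
  S <- matrix(params$holding_mv, n, n_cells)
  spike_times <- vector("list", n_cells)
  for (cl in seq_len(n_cells)) {
    st <- slot_onsets[cl] + (seq_len(n_pulses) - 1L) / pulse_rate
    spike_times[[cl]] <- st + shp$peak_ms / 1000
    for (s0 in st) {
      i0 <- round(s0 * rate) + 1L
      idx <- i0:min(n, i0 + length(shp$wave) - 1L)
      S[idx, cl] <- S[idx, cl] + shp$wave[seq_along(idx)]
    }
  }

  kern <- pspKernel(rise_ms, decay_ms, rate)
  lk <- length(kern)
  edges <- which(A, arr.ind = TRUE)
  ncol_all <- n_cells * n_sweeps
  if (noise_sd_mv > 0) {
    bf <- signal::butter(4, 2 * 6000 / rate, type = "low")
    dat <- .gaussLowpassMatrix(n, ncol_all, noise_sd_mv, bf$b, bf$a,
                               noise_sd_mv)
    dat <- dat + as.vector(S)      # recycles S over sweeps column-block-wise
  } else {
    dat <- matrix(rep(as.vector(S), n_sweeps), n, ncol_all)
  }
  if (nrow(edges) > 0) {
    for (sw in seq_len(n_sweeps)) {
      off <- (sw - 1L) * n_cells
      for (e in seq_len(nrow(edges))) {
        pre <- edges[e, 1L]; post <- edges[e, 2L]
        for (ts in spike_times[[pre]]) {
          scale <- amp[pre, post] *
            (if (trial_cv > 0) .rlnormMeanSd(1L, 1, trial_cv) else 1)
          i0 <- round((ts + lat[pre, post] / 1000) * rate) + 1L
          idx <- i0:min(n, i0 + lk - 1L)
          dat[idx, off + post] <- dat[idx, off + post] +
            scale * kern[seq_along(idx)]
        }
      }
    }
  }
  dim(dat) <- c(n, n_cells, n_sweeps)
  proto <- list(slot_onset_s = slot_onsets, slot_length_s = slot_len,
                n_pulses = n_pulses, pulse_rate_hz = pulse_rate,
                stim_amplitude_na = 2, stim_width_ms = 2,
                spike_times_s = spike_times, holding_mv = params$holding_mv,
                gap_s = gap_s, ap = shp[c("threshold_ms", "threshold_mv",
                                          "peak_ms", "peak_mv",
                                          "halfwidth_ms")])
  new("SweepSet", data = dat, rate = rate, protocol = proto,
      seed = as.integer(seed), groundTruth = gt)
}
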