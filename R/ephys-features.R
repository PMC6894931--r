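#' Resting membrane potential from a baseline window
#'
#' Mean voltage over the first \code{baseline_ms} of a current-clamp trace.
#'
#' @param trace a current-clamp \linkS4class{Trace}.
#' @param baseline_ms baseline window, ms (default 100).
#' @return resting potential, mV.
#' @export
restingPotential <- function(trace, baseline_ms = 100) {
  stopifnot(is(trace, "Trace"))
  if (clampMode(trace) != "current")
    stop("resting potential requires a current-clamp trace", call. = FALSE)
  nb <- round(baseline_ms / 1000 * sampleRate(trace))
  if (nb < 1L || nb > length(trace))
    stop("baseline window exceeds the trace", call. = FALSE)
  mean(traceSamples(trace)[seq_len(nb)])
}

#' Access and input resistance from a voltage-clamp test pulse
#'
#' From the current response to a square test pulse (default 200 ms, 10 mV):
#' Ra = dV / (I_peak - I_baseline) with I_peak the extremum within the first
#' \code{peak_window_ms} after onset, and the series-resistance-corrected
#' Rin = dV / (I_ss - I_baseline) - Ra with I_ss the mean over the last
#' \code{ss_frac} of the pulse. Set \code{corrected = FALSE} for the
#' uncorrected total resistance instead.
#'
#' @param trace voltage-clamp \linkS4class{Trace} (pA).
#' @param dv_mv step amplitude, mV.
#' @param onset_s,width_s pulse onset and width, seconds.
#' @param peak_window_ms search window for the capacitive peak (default 10).
#' @param ss_frac trailing fraction of the pulse used for steady state
#'   (default 0.2).
#' @param corrected subtract Ra from the steady-state resistance (default).
#' @return list: \code{ra_mohm}, \code{rin_mohm}, \code{i_peak_pa},
#'   \code{i_ss_pa}, \code{i_base_pa}, \code{flag} (NA, or
#'   \code{"non-physical"} when I_ss <= I_baseline, or \code{"rin-infinite"}
#'   when I_peak ~ I_ss).
#' @export
measureResistances <- function(trace, dv_mv = 10, onset_s, width_s,
                               peak_window_ms = 10, ss_frac = 0.2,
                               corrected = TRUE) {
  stopifnot(is(trace, "Trace"))
  if (clampMode(trace) != "voltage")
    stop("resistance measurement requires a voltage-clamp trace",
         call. = FALSE)
  x <- traceSamples(trace); fs <- sampleRate(trace)
  i_on <- round(onset_s * fs) + 1L
  i_off <- round((onset_s + width_s) * fs)
  if (i_on <= 1L || i_off > length(x))
    stop("pulse window exceeds the trace", call. = FALSE)
  i_base <- mean(x[max(1L, i_on - round(0.02 * fs)):(i_on - 1L)])
  pk_end <- min(i_off, i_on + round(peak_window_ms / 1000 * fs))
  seg <- x[i_on:pk_end]
  i_peak <- seg[which.max(abs(seg - i_base))]
  ss_start <- i_off - round(ss_frac * (i_off - i_on + 1L)) + 1L
  i_ss <- mean(x[ss_start:i_off])
  if (i_ss <= i_base)
    return(list(ra_mohm = NA_real_, rin_mohm = NA_real_, i_peak_pa = i_peak,
                i_ss_pa = i_ss, i_base_pa = i_base, flag = "non-physical"))
  ra <- 1000 * dv_mv / (i_peak - i_base)        # mV/pA -> GOhm; x1000 = MOhm
  r_tot <- 1000 * dv_mv / (i_ss - i_base)
  flag <- NA_character_
  rin <- if (corrected) r_tot - ra else r_tot
  if (corrected && rin <= 0) { rin <- Inf; flag <- "rin-infinite" }
  list(ra_mohm = ra, rin_mohm = rin, i_peak_pa = i_peak, i_ss_pa = i_ss,
       i_base_pa = i_base, flag = flag)
}

# central-difference derivative in mV/ms
.dvdt <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d * fs / 1000
}

#' Detect action potentials in a current-clamp trace
#'
#' Local maxima with a peak of at least \code{peak_min_mv} (default 0 mV)
#' preceded within 1 ms by a depolarisation rate of at least
#' \code{slope_min} (default 20 mV/ms), with a refractory separation.
#'
#' @param trace current-clamp \linkS4class{Trace}.
#' @param peak_min_mv minimum peak voltage, mV.
#' @param slope_min minimum preceding dV/dt, mV/ms.
#' @param refractory_ms minimum peak separation, ms (default 2).
#' @return integer vector of spike peak sample indices.
#' @export
detectSpikes <- function(trace, peak_min_mv = 0, slope_min = 20,
                         refractory_ms = 2) {
  stopifnot(is(trace, "Trace"))
  x <- traceSamples(trace); fs <- sampleRate(trace)
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- .dvdt(x, fs)
  pk <- which(x[2:(n - 1L)] >= x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n] &
              x[2:(n - 1L)] >= peak_min_mv) + 1L
  look <- round(0.001 * fs)
  pk <- pk[vapply(pk, function(i)
    max(d[max(1L, i - look):i]) >= slope_min, logical(1))]
  if (length(pk) < 2L) return(pk)
  keep <- pk[1L]
  gap <- refractory_ms / 1000 * fs
  for (i in pk[-1L]) if (i - keep[length(keep)] >= gap) keep <- c(keep, i)
  keep
}

#' Action-potential features of one spike
#'
#' Threshold is the voltage at the first sample — searching backward from
#' the peak — where dV/dt exceeds the baseline slope by 10 mV/ms; amplitude
#' is peak minus threshold; half-width is the duration spent above
#' threshold + amplitude/2 (sub-sample, linearly interpolated); the
#' depolarisation and repolarisation rates are the extremal dV/dt between
#' threshold and peak and between peak and the return to threshold.
#'
#' @param trace current-clamp \linkS4class{Trace}.
#' @param spike_idx peak sample index (from \code{\link{detectSpikes}}).
#' @param baseline_slope baseline dV/dt to offset the 10 mV/ms criterion
#'   (mV/ms; ~0 for a held cell). With \code{baseline_slope = NULL} the
#'   median dV/dt over the 10 ms before the spike is used.
#' @param window_ms search window before/after the peak (default 10).
#' @return list: \code{threshold_mv}, \code{peak_mv}, \code{amplitude_mv},
#'   \code{half_width_ms}, \code{max_depol_rate}, \code{max_repol_rate},
#'   \code{spike_time_s}, \code{threshold_idx}.
#' @export
apFeatures <- function(trace, spike_idx, baseline_slope = 0,
                       window_ms = 10) {
  stopifnot(is(trace, "Trace"))
  x <- traceSamples(trace); fs <- sampleRate(trace)
  w <- round(window_ms / 1000 * fs)
  lo <- max(1L, spike_idx - w); hi <- min(length(x), spike_idx + w)
  d <- .dvdt(x, fs)
  if (is.null(baseline_slope))
    baseline_slope <- stats::median(d[lo:max(lo, spike_idx - round(0.002 * fs))])
  crit <- baseline_slope + 10
  i <- spike_idx
  while (i > lo && d[i - 1L] >= crit) i <- i - 1L
  if (i == spike_idx || d[i] < crit)
    stop("feature-undefined: no 10 mV/ms threshold crossing found",
         call. = FALSE)
  thr_idx <- i
  thr <- x[thr_idx]
  peak <- x[spike_idx]
  amp <- peak - thr
  v_half <- thr + amp / 2
  up <- .crossTime(x, thr_idx, spike_idx, v_half, rising = TRUE)
  j <- spike_idx
  while (j < hi && x[j] > thr) j <- j + 1L
  dn <- .crossTime(x, spike_idx, j, v_half, rising = FALSE)
  hw <- (dn - up) / fs * 1000
  list(threshold_mv = thr, peak_mv = peak, amplitude_mv = amp,
       half_width_ms = hw,
       max_depol_rate = max(d[thr_idx:spike_idx]),
       max_repol_rate = min(d[spike_idx:j]),
       spike_time_s = (spike_idx - 1L) / fs,
       threshold_idx = thr_idx)
}

# sub-sample crossing of level v between indices a..b (fractional index)
.crossTime <- function(x, a, b, v, rising) {
  idx <- a:b
  cross <- if (rising) which(x[idx[-length(idx)]] < v & x[idx[-1L]] >= v)
           else which(x[idx[-length(idx)]] >= v & x[idx[-1L]] < v)
  if (!length(cross)) return(if (rising) a else b)
  i <- idx[cross[1L]]
  frac <- (v - x[i]) / (x[i + 1L] - x[i])
  i + frac
}

#' Choose the stimulation amplitude and duration at rheobase
#'
#' The adjustment protocol scans amplitudes 0.5 to 4 nA in 0.5 nA steps at
#' 1 ms duration, escalating the duration only when no amplitude elicits a
#' spike. The chosen stimulus is the second-lowest spiking amplitude at the
#' final duration — i.e. the lowest spiking amplitude plus one 0.5 nA step —
#' capped at 4 nA.
#'
#' @param grid data.frame with columns \code{amplitude_na},
#'   \code{duration_ms}, \code{spiked} (logical).
#' @return list: \code{amplitude_na}, \code{duration_ms}.
#' @export
selectRheobaseStimulus <- function(grid) {
  stopifnot(all(c("amplitude_na", "duration_ms", "spiked") %in% names(grid)))
  if (!any(grid$spiked))
    stop("stimulus-not-found: no spiking combination in the grid",
         call. = FALSE)
  durs <- sort(unique(grid$duration_ms))
  for (d in durs) {
    g <- grid[grid$duration_ms == d & grid$spiked, , drop = FALSE]
    if (nrow(g) > 0L) {
      a <- min(g$amplitude_na) + 0.5
      return(list(amplitude_na = min(a, 4), duration_ms = d))
    }
  }
}

#' Quality-control filter for recorded cells
#'
#' Excludes cells whose resting membrane potential is more positive than
#' the cutoff (strictly greater than -60 mV by default) or whose access
#' resistance is not below the cutoff (40 MOhm by default; Ra = 40 fails).
#'
#' @param cells data.frame with columns \code{rmp_mV} and \code{ra_MOhm}
#'   (additional columns pass through).
#' @param rmp_cutoff_mv RMP cutoff, mV.
#' @param ra_cutoff_mohm access-resistance cutoff, MOhm.
#' @return the input with logical \code{included} and character
#'   \code{exclusion_reason} columns (";"-joined reasons among
#'   \code{rmp_above_cutoff}, \code{high_access_resistance}); the cutoffs
#'   are attached as attribute \code{thresholds}.
#' @examples
#' qcFilter(data.frame(rmp_mV = c(-65, -58), ra_MOhm = c(20, 20)))$included
#' @export
qcFilter <- function(cells, rmp_cutoff_mv = -60, ra_cutoff_mohm = 40) {
  if (!all(c("rmp_mV", "ra_MOhm") %in% names(cells)))
    stop("invalid-table: need columns rmp_mV and ra_MOhm", call. = FALSE)
  bad_rmp <- cells$rmp_mV > rmp_cutoff_mv
  bad_ra <- cells$ra_MOhm >= ra_cutoff_mohm
  reasons <- mapply(function(r, a)
    paste(c(if (r) "rmp_above_cutoff", if (a) "high_access_resistance"),
          collapse = ";"),
    bad_rmp, bad_ra)
  cells$included <- !(bad_rmp | bad_ra)
  cells$exclusion_reason <- ifelse(cells$included, NA_character_, reasons)
  attr(cells, "thresholds") <- c(rmp_cutoff_mv = rmp_cutoff_mv,
                                 ra_cutoff_mohm = ra_cutoff_mohm)
  cells
}
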