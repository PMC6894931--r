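#' Clements-Bekkers template-scaling detection criterion
#'
#' Slides a PSP-shaped template along the trace; at each offset the
#' template is fitted to the data by closed-form least squares over scale
#' and offset. The detection criterion is the fitted scale divided by the
#' standard error of the fit, sqrt(SSE/(N-1)). Perfect fits (SSE ~ 0) are
#' capped at a large sentinel rather than returning infinity.
#'
#' @param trace a \linkS4class{Trace} (or numeric vector).
#' @param template numeric template, shorter than the trace (unit peak by
#'   convention, see \code{\link{pspKernel}}).
#' @param cap sentinel value replacing near-infinite criteria.
#' @return list: \code{criterion}, \code{scale}, \code{offset}, \code{se}
#'   — numeric vectors of length (trace - template + 1); element i refers
#'   to the window starting at sample i.
#' @export
cbCriterion <- function(trace, template, cap = 1e6) {
  y <- if (is(trace, "Trace")) traceSamples(trace) else as.numeric(trace)
  tm <- as.numeric(template)
  n <- length(y); m <- length(tm)
  if (m >= n) stop("template must be shorter than the trace", call. = FALSE)
  st <- sum(tm); st2 <- sum(tm^2)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  nw <- n - m + 1L
  sy <- cs[(m + 1L):(n + 1L)] - cs[1:nw]        # window sums
  sy2 <- cs2[(m + 1L):(n + 1L)] - cs2[1:nw]
  f <- stats::filter(y, rev(tm), sides = 1)      # cross-correlation
  sty <- as.numeric(f[m:n])
  denom <- m * st2 - st^2
  scale <- (m * sty - st * sy) / denom
  offset <- (sy - scale * st) / m
  sse <- sy2 + scale^2 * st2 + m * offset^2 -
    2 * scale * sty - 2 * offset * sy + 2 * scale * offset * st
  sse[sse < 0] <- 0                              # numerical floor
  se <- sqrt(sse / (m - 1L))
  criterion <- ifelse(se > 0, scale / se, sign(scale) * cap)
  criterion <- pmax(pmin(criterion, cap), -cap)
  # flat windows give 0/0-like ratios; a vanishing scale is no event
  criterion[abs(scale) < 1e-8 * max(diff(range(y)), .Machine$double.eps)] <- 0
  list(criterion = criterion, scale = scale, offset = offset, se = se)
}

#' Detection template for spontaneous-event matching
#'
#' A truncated unit-peak PSP kernel. Short templates are deliberate: the
#' sliding fit degrades when a neighbouring event falls inside the fitted
#' window, so the template spans only the rise and the early decay
#' (rise + 0.65 decay by default, ~15 ms for 2/20 ms kinetics) while still
#' containing the peak.
#'
#' @param rise_ms,decay_ms PSP kinetics (ms).
#' @param rate sampling rate, Hz.
#' @param span_ms template span (ms); default rise + 0.65 * decay.
#' @return numeric unit-peak template.
#' @export
cbTemplate <- function(rise_ms = 2, decay_ms = 20, rate = 20000,
                       span_ms = rise_ms + 0.65 * decay_ms) {
  k <- pspKernel(rise_ms, decay_ms, rate)
  n <- min(length(k), round(span_ms / 1000 * rate))
  k <- k[seq_len(n)]
  attr(k, "peak_time_ms") <- NULL
  k / max(k)
}

#' Detect spontaneous EPSPs by template scaling
#'
#' Events are local maxima of the \code{\link{cbCriterion}} series above
#' \code{threshold} (default 4), separated by a refractory interval.
#' Event amplitude is the fitted scale times the template peak (= the scale
#' for a unit-peak template); the event time is the window onset.
#'
#' @param trace current-clamp resting \linkS4class{Trace} (2 s typical).
#' @param template unit-peak PSP template (default
#'   \code{\link{cbTemplate}} at the trace's rate).
#' @param threshold detection-criterion threshold.
#' @param refractory_ms minimum event separation, ms (default 5).
#' @return list: \code{events} data.frame (\code{time_s},
#'   \code{amplitude_mv}, \code{criterion}), \code{median_amplitude_mv},
#'   \code{frequency_hz}.
#' @export
detectSpontEvents <- function(trace, template = NULL, threshold = 4,
                              refractory_ms = 5) {
  stopifnot(is(trace, "Trace"))
  fs <- sampleRate(trace)
  if (is.null(template)) template <- cbTemplate(rate = fs)
  cb <- cbCriterion(trace, template)
  cr <- cb$criterion
  # one event per contiguous supra-threshold segment, at the criterion
  # maximum; segments closer than the refractory interval are merged
  above <- cr >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  keep <- integer(0)
  gap <- refractory_ms / 1000 * fs
  if (nrow(seg)) {
    for (s in seq_len(nrow(seg))) {
      i <- seg[s, 1L] + which.max(cr[seg[s, 1L]:seg[s, 2L]]) - 1L
      if (!length(keep) || i - keep[length(keep)] >= gap)
        keep <- c(keep, i)
    }
  }
  peak <- max(template)
  ev <- data.frame(time_s = (keep - 1L) / fs,
                   amplitude_mv = cb$scale[keep] * peak,
                   criterion = cr[keep])
  dur <- length(trace) / fs
  list(events = ev,
       median_amplitude_mv = if (nrow(ev)) stats::median(ev$amplitude_mv)
                             else NA_real_,
       frequency_hz = nrow(ev) / dur)
}

#' Average the sweeps of one channel
#'
#' Pointwise mean across sweeps; the number averaged is attached as
#' attribute \code{n_averaged} on the returned trace's samples.
#'
#' @param sweeps a \linkS4class{SweepSet}.
#' @param channel channel (cell) index.
#' @return a \linkS4class{Trace} with attribute \code{n_averaged}.
#' @export
averageSweeps <- function(sweeps, channel) {
  stopifnot(is(sweeps, "SweepSet"))
  avg <- rowMeans(sweeps@data[, channel, , drop = FALSE], dims = 1L)
  tr <- Trace(avg, rate = sweeps@rate, clampMode = "current")
  attr(tr@samples, "n_averaged") <- nSweeps(sweeps)
  tr
}

#' Call a synaptic connection from a sweep-averaged trace
#'
#' The amplitude is the extremum of the baseline-subtracted averaged trace
#' within the response window after the FIRST presynaptic spike (later
#' pulses of the 20 Hz train are reported as paired-pulse information but do
#' not enter the call). The trace is lightly smoothed (boxcar,
#' \code{smooth_ms}) before measurement so the extremum is not dominated by
#' single-sample noise. A pair is called connected when |amplitude| reaches
#' \code{k_sd} times the baseline SD of the (smoothed) averaged trace AND
#' the latency — the 10 percent rise point relative to the spike — falls in
#' the monosynaptic gate. When screening many pairs, raise \code{k_sd}
#' (e.g. to 5) to control family-wise false positives; see the package
#' vignette.
#'
#' @param avg_trace averaged \linkS4class{Trace}
#'   (\code{\link{averageSweeps}}).
#' @param spike_times_s presynaptic spike (peak) times, seconds.
#' @param baseline_window_s length-2 window (s) preceding the first spike
#'   used for the baseline mean and SD (default: the 50 ms before it).
#' @param response_window_ms length-2 window after the first spike searched
#'   for the response (default c(0.5, 15)).
#' @param k_sd detection threshold in baseline SDs (default 3).
#' @param latency_gate_ms monosynaptic latency gate (default c(0.5, 5)).
#' @param sign expected PSP sign: \code{"positive"} (EPSP at -60 mV),
#'   \code{"negative"}, or \code{"both"}.
#' @param smooth_ms boxcar smoothing window, ms (0 disables).
#' @return list: \code{connected}, \code{amplitude_mv} (signed),
#'   \code{latency_ms}, \code{snr}, \code{baseline_sd_mv},
#'   \code{paired_pulse_mv} (amplitudes after each later spike),
#'   \code{n_sweeps}, \code{k_sd}.
#' @export
callConnection <- function(avg_trace, spike_times_s,
                           baseline_window_s = NULL,
                           response_window_ms = c(0.5, 15), k_sd = 3,
                           latency_gate_ms = c(0.5, 5), sign = "positive",
                           smooth_ms = 0.75) {
  stopifnot(is(avg_trace, "Trace"), length(spike_times_s) >= 1L)
  fs <- sampleRate(avg_trace)
  x <- traceSamples(avg_trace)
  n_avg <- attr(x, "n_averaged")
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / 1000 * fs))
    if (w %% 2L == 0L) w <- w + 1L
    sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    half <- (w - 1L) %/% 2L
    sm[seq_len(half)] <- x[seq_len(half)]
    sm[(length(x) - half + 1L):length(x)] <- x[(length(x) - half + 1L):length(x)]
    x <- sm
  }
  t1 <- min(spike_times_s)
  if (is.null(baseline_window_s)) baseline_window_s <- c(t1 - 0.05, t1 - 0.001)
  bi <- round(baseline_window_s * fs) + 1L
  if (bi[1L] < 1L || bi[2L] >= round(t1 * fs))
    stop("baseline window must precede the first spike", call. = FALSE)
  base <- x[bi[1L]:bi[2L]]
  b_mean <- mean(base); b_sd <- stats::sd(base)
  measure <- function(ts) {
    wi <- round((ts + response_window_ms / 1000) * fs) + 1L
    if (wi[2L] > length(x))
      stop("response window exceeds the trace", call. = FALSE)
    seg <- x[wi[1L]:wi[2L]] - b_mean
    pk <- switch(sign,
                 positive = which.max(seg),
                 negative = which.min(seg),
                 both = which.max(abs(seg)))
    amp <- seg[pk]
    # 10% rise point: last crossing of 0.1*amp before the extremum
    pre <- seg[seq_len(pk)]
    below <- which(abs(pre) < 0.1 * abs(amp))
    onset <- if (length(below)) max(below) else 1L
    lat <- (wi[1L] - 1L + onset - 1L) / fs - ts
    c(amp = amp, lat_ms = lat * 1000)
  }
  first <- measure(t1)
  later <- if (length(spike_times_s) > 1L)
    vapply(sort(spike_times_s)[-1L], function(ts) measure(ts)[["amp"]],
           numeric(1))
  else numeric(0)
  snr <- if (b_sd > 0) abs(first[["amp"]]) / b_sd
         else if (abs(first[["amp"]]) > 0) Inf else 0
  connected <- snr >= k_sd &&
    first[["lat_ms"]] >= latency_gate_ms[1L] &&
    first[["lat_ms"]] <= latency_gate_ms[2L]
  list(connected = connected, amplitude_mv = unname(first[["amp"]]),
       latency_ms = unname(first[["lat_ms"]]), snr = unname(snr),
       baseline_sd_mv = b_sd, paired_pulse_mv = unname(later),
       n_sweeps = if (is.null(n_avg)) NA_integer_ else n_avg,
       k_sd = k_sd)
}

#' Screen every ordered pair of a sweep set for connections
#'
#' Averages the sweeps of each channel, finds the presynaptic spikes of
#' each cell's stimulation slot (\code{\link{detectSpikes}} on the averaged
#' presynaptic channel), and calls every ordered (pre, post) pair with
#' \code{\link{callConnection}}.
#'
#' @param sweeps a \linkS4class{SweepSet}.
#' @param session session index used to qualify cell ids (default 1).
#' @param ... passed to \code{\link{callConnection}} (e.g. \code{k_sd}).
#' @return data.frame of calls: pre_id, post_id, pre, post, connected,
#'   amplitude_mV, latency_ms, snr, n_sweeps.
#' @export
detectConnections <- function(sweeps, session = 1L, ...) {
  stopifnot(is(sweeps, "SweepSet"))
  nc <- nChannels(sweeps)
  fs <- sampleRate(sweeps)
  proto <- sweeps@protocol
  avgs <- lapply(seq_len(nc), function(ch) averageSweeps(sweeps, ch))
  slots <- proto$slot_onset_s
  slot_len <- proto$slot_length_s
  out <- vector("list", nc * (nc - 1L))
  k <- 0L
  for (pre in seq_len(nc)) {
    # presynaptic spikes within this cell's own stimulation slot
    spk_idx <- detectSpikes(avgs[[pre]])
    spk_t <- (spk_idx - 1L) / fs
    spk_t <- spk_t[spk_t >= slots[pre] - 0.005 &
                   spk_t <= slots[pre] + slot_len + 0.005]
    for (post in seq_len(nc)) {
      if (post == pre) next
      cc <- callConnection(avgs[[post]], spk_t, ...)
      k <- k + 1L
      out[[k]] <- data.frame(
        pre_id = sprintf("%d.%d", pre, session),
        post_id = sprintf("%d.%d", post, session),
        pre = pre, post = post, connected = cc$connected,
        amplitude_mV = cc$amplitude_mv, latency_ms = cc$latency_ms,
        snr = cc$snr, n_sweeps = cc$n_sweeps,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Assemble a connectivity result over a session plan
#'
#' Checks that the calls cover exactly the ordered pairs mandated by the
#' plan's tested mask (\code{\link{planSummary}}), then assembles the
#' tested/connected/amplitude/latency matrices and intersomatic distances.
#'
#' @param calls data.frame of calls with columns \code{pre_id},
#'   \code{post_id}, \code{connected}, \code{amplitude_mV},
#'   \code{latency_ms} (as from \code{\link{detectConnections}}).
#' @param plan a \linkS4class{SessionPlan}.
#' @param positions optional n x 3 matrix of soma positions (um), rows in
#'   tested-mask cell order.
#' @return a \linkS4class{ConnectivityResult}.
#' @export
buildConnectivity <- function(calls, plan, positions = NULL) {
  ps <- planSummary(plan)
  mask <- ps$tested_mask
  ids <- rownames(mask)
  want <- outer(ids, ids, paste)[mask]
  have <- paste(calls$pre_id, calls$post_id)
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra))
    stop(sprintf(
      "coverage-mismatch: %s%s",
      if (length(missing)) paste0("missing pairs: ",
        paste(utils::head(missing, 10L), collapse = ", ")) else "",
      if (length(extra)) paste0(" extra pairs: ",
        paste(utils::head(extra, 10L), collapse = ", ")) else ""),
      call. = FALSE)
  n <- length(ids)
  conn <- matrix(FALSE, n, n, dimnames = dimnames(mask))
  amp <- matrix(NA_real_, n, n, dimnames = dimnames(mask))
  lat <- matrix(NA_real_, n, n, dimnames = dimnames(mask))
  ii <- match(calls$pre_id, ids); jj <- match(calls$post_id, ids)
  conn[cbind(ii, jj)] <- calls$connected
  amp[cbind(ii, jj)] <- calls$amplitude_mV
  lat[cbind(ii, jj)] <- calls$latency_ms
  if (is.null(positions)) {
    dm <- matrix(NA_real_, n, n)
  } else {
    dm <- as.matrix(stats::dist(positions))
  }
  dimnames(dm) <- dimnames(mask)
  new("ConnectivityResult", cellIds = ids, tested = mask, connected = conn,
      amplitude = amp, latency = lat, distances = dm, plan = plan)
}
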