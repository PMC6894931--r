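#' Trace: a sampled electrophysiological recording
#'
#' A single-channel recording with a fixed sampling rate and clamp mode.
#' Samples are millivolts in current clamp and picoamperes in voltage clamp.
#'
#' @slot samples numeric vector of samples (mV or pA).
#' @slot rate sampling rate in Hz (default 20000).
#' @slot clampMode either \code{"current"} or \code{"voltage"}.
#' @slot t0 time of the first sample in seconds.
#'
#' @examples
#' tr <- Trace(rep(-65, 2000))
#' traceSamples(tr)[1:3]
#' sampleRate(tr)
#' @export
setClass("Trace",
  representation(samples = "numeric", rate = "numeric",
                 clampMode = "character", t0 = "numeric"),
  prototype(rate = 20000, clampMode = "current", t0 = 0))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@samples) < 1L) msg <- c(msg, "trace must contain samples")
  if (!all(is.finite(object@samples))) msg <- c(msg, "all samples must be finite")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (!object@clampMode %in% c("current", "voltage"))
    msg <- c(msg, "clampMode must be 'current' or 'voltage'")
  if (length(msg)) msg else TRUE
})

#' Construct a Trace
#'
#' @param samples numeric vector (mV in current clamp, pA in voltage clamp).
#' @param rate sampling rate in Hz.
#' @param clampMode \code{"current"} or \code{"voltage"}.
#' @param t0 time of first sample, seconds.
#' @return a \linkS4class{Trace}.
#' @export
Trace <- function(samples, rate = 20000, clampMode = "current", t0 = 0) {
  new("Trace", samples = as.numeric(samples), rate = rate,
      clampMode = clampMode, t0 = t0)
}

#' GroundTruthNetwork: known connectivity behind a synthetic cluster
#'
#' Directed ground truth used to score the detection pipeline: adjacency,
#' unitary amplitudes (mV), synaptic latencies (ms), kinetics, trial-to-trial
#' coefficient of variation and soma positions (um).
#'
#' @slot adjacency logical matrix, \code{[pre, post]}, diagonal FALSE.
#' @slot amplitude numeric matrix of unitary PSP amplitudes (mV); positive
#'   where an edge exists, 0 elsewhere.
#' @slot latency numeric matrix of synaptic latencies (ms).
#' @slot rise,decay numeric matrices of PSP kinetics (ms).
#' @slot trialCV trial-to-trial coefficient of variation (fraction).
#' @slot positions n x 3 matrix of soma positions (um).
#' @export
setClass("GroundTruthNetwork",
  representation(adjacency = "matrix", amplitude = "matrix",
                 latency = "matrix", rise = "matrix", decay = "matrix",
                 trialCV = "numeric", positions = "matrix"))

setValidity("GroundTruthNetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (any(diag(A))) msg <- c(msg, "adjacency diagonal must be FALSE")
  if (any(object@amplitude[A] <= 0))
    msg <- c(msg, "amplitude must be positive on true edges")
  if (any(object@latency[A] <= 0))
    msg <- c(msg, "latency must be positive on true edges")
  if (nrow(object@positions) != nrow(A) || ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be n x 3")
  if (length(msg)) msg else TRUE
})

#' SweepSet: a grid of sweeps by channels with a stimulation protocol
#'
#' Synthetic or recorded multi-channel current-clamp data stored as a
#' samples x channels x sweeps array, together with the per-cell stimulation
#' protocol and, for synthetic data, the generating ground truth.
#'
#' @slot data numeric array \code{[sample, channel, sweep]} (mV).
#' @slot rate sampling rate, Hz.
#' @slot protocol list with the per-cell stimulation slots (see
#'   \code{\link{synthCluster}}): \code{slot_onset_s}, \code{n_pulses},
#'   \code{pulse_rate_hz}, \code{slot_length_s}, and the AP parameters.
#' @slot seed integer seed the set was generated from (NA for recorded data).
#' @slot groundTruth a \linkS4class{GroundTruthNetwork} or NULL.
#' @export
setClass("SweepSet",
  representation(data = "array", rate = "numeric", protocol = "list",
                 seed = "integer", groundTruth = "ANY"),
  prototype(seed = NA_integer_, groundTruth = NULL))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a samples x channels x sweeps array")
  if (!all(is.finite(object@data))) msg <- c(msg, "all samples must be finite")
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  gt <- object@groundTruth
  if (!is.null(gt) && nrow(gt@adjacency) != dim(object@data)[2L])
    msg <- c(msg, "ground-truth size must match channel count")
  if (length(msg)) msg else TRUE
})

#' SessionPlan: patched and maintained cells per recording session
#'
#' A clean-to-extend experiment is an ordered list of recording sessions;
#' each session patches \code{n_new} fresh cells while \code{n_old} cells
#' are maintained from previous sessions. The first session maintains none.
#'
#' @slot sessions data.frame with integer columns \code{n_new}, \code{n_old}.
#' @slot nPipettes available pipette count.
#'
#' @examples
#' plan <- SessionPlan(list(c(8, 0), c(4, 4), c(5, 3)), nPipettes = 8)
#' planSummary(plan)$total_tested
#' @export
setClass("SessionPlan",
  representation(sessions = "data.frame", nPipettes = "integer"))

setValidity("SessionPlan", function(object) {
  s <- object@sessions
  msg <- character()
  if (!all(c("n_new", "n_old") %in% names(s)))
    return("sessions needs columns n_new and n_old")
  if (nrow(s) < 1L) msg <- c(msg, "at least one session required")
  if (any(s$n_new < 0) || any(s$n_old < 0))
    msg <- c(msg, "n_new and n_old must be non-negative")
  if (any(s$n_new + s$n_old > object@nPipettes))
    msg <- c(msg, "n_new + n_old must not exceed n_pipettes")
  if (nrow(s) >= 1L && s$n_old[1L] != 0L)
    msg <- c(msg, "first session must have n_old = 0")
  if (nrow(s) >= 2L) {
    prior <- cumsum(s$n_new)
    if (any(s$n_old[-1L] > prior[-nrow(s)]))
      msg <- c(msg, "n_old cannot exceed cells recorded in prior sessions")
    # a released cell is lost: maintained cells must have been held in the
    # immediately preceding session
    held_before <- s$n_new[-nrow(s)] + s$n_old[-nrow(s)]
    if (any(s$n_old[-1L] > held_before))
      msg <- c(msg,
        "n_old cannot exceed the cells held in the previous session")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SessionPlan
#'
#' @param sessions either a data.frame with columns \code{n_new}, \code{n_old}
#'   or a list of length-2 vectors \code{c(n_new, n_old)}.
#' @param nPipettes available pipette count.
#' @return a \linkS4class{SessionPlan}.
#' @export
SessionPlan <- function(sessions, nPipettes) {
  if (is.list(sessions) && !is.data.frame(sessions)) {
    sessions <- data.frame(
      n_new = vapply(sessions, function(x) as.integer(x[1L]), integer(1)),
      n_old = vapply(sessions, function(x) as.integer(x[2L]), integer(1)))
  }
  sessions$n_new <- as.integer(sessions$n_new)
  sessions$n_old <- as.integer(sessions$n_old)
  new("SessionPlan", sessions = sessions, nPipettes = as.integer(nPipettes))
}

#' RigidTransform: manipulator-to-microscope frame mapping
#'
#' A proper rigid transform p -> R p + t fitted by orthogonal Procrustes
#' (Kabsch) with the residual RMS of the fit.
#'
#' @slot rotation 3 x 3 proper rotation matrix (det = +1).
#' @slot translation length-3 translation (um).
#' @slot rms residual root-mean-square of the fit (um).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric", rms = "numeric"),
  prototype(rms = 0))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (det = +1)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' ConnectivityResult: tested and found directed pairs across sessions
#'
#' Assembled output of connection calling over a clean-to-extend experiment.
#' Cell identifiers are session-qualified, \code{"<cellIndex>.<sessionIndex>"}
#' (cell 9 patched in session 2 is \code{"9.2"}).
#'
#' @slot cellIds character vector of session-qualified cell ids.
#' @slot tested,connected logical matrices \code{[pre, post]}.
#' @slot amplitude,latency numeric matrices (mV, ms; NA where untested).
#' @slot distances numeric matrix of intersomatic distances (um).
#' @slot plan the \linkS4class{SessionPlan} that produced the tested mask.
#' @export
setClass("ConnectivityResult",
  representation(cellIds = "character", tested = "matrix",
                 connected = "matrix", amplitude = "matrix",
                 latency = "matrix", distances = "matrix", plan = "ANY"))

setValidity("ConnectivityResult", function(object) {
  msg <- character()
  n <- length(object@cellIds)
  for (nm in c("tested", "connected", "amplitude", "latency", "distances")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n))) msg <- c(msg, paste(nm, "must be n x n"))
  }
  if (any(diag(object@tested))) msg <- c(msg, "diagonal must be untested")
  if (any(object@connected & !object@tested))
    msg <- c(msg, "connected pairs must be tested")
  if (length(msg)) msg else TRUE
})
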