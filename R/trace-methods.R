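#' @describeIn Trace samples as a numeric vector
#' @param object a \linkS4class{Trace}
#' @export
setMethod("traceSamples", "Trace", function(object) object@samples)

#' @describeIn Trace sampling rate in Hz
#' @export
setMethod("sampleRate", "Trace", function(object) object@rate)

#' @describeIn Trace clamp mode ("current" or "voltage")
#' @export
setMethod("clampMode", "Trace", function(object) object@clampMode)

#' @describeIn Trace sample times in seconds
#' @export
setMethod("time", "Trace", function(x, ...) {
  x@t0 + (seq_along(x@samples) - 1L) / x@rate
})

setMethod("length", "Trace", function(x) length(x@samples))

setMethod("show", "Trace", function(object) {
  unit <- if (object@clampMode == "current") "mV" else "pA"
  cat(sprintf("Trace: %d samples @ %g kHz, %s clamp (%s), %.3f s\n",
              length(object@samples), object@rate / 1000, object@clampMode,
              unit, length(object@samples) / object@rate))
})

#' @describeIn SweepSet number of sweeps
#' @param object a \linkS4class{SweepSet}
#' @export
setMethod("nSweeps", "SweepSet", function(object) dim(object@data)[3L])

#' @describeIn SweepSet number of channels (= cells)
#' @export
setMethod("nChannels", "SweepSet", function(object) dim(object@data)[2L])

#' @describeIn SweepSet sampling rate in Hz
#' @export
setMethod("sampleRate", "SweepSet", function(object) object@rate)

#' @describeIn SweepSet generating ground truth (or NULL)
#' @export
setMethod("groundTruth", "SweepSet", function(object) object@groundTruth)

#' Extract one sweep/channel from a SweepSet as a Trace
#'
#' @param x a \linkS4class{SweepSet}
#' @param channel channel (cell) index
#' @param sweep sweep index
#' @return a \linkS4class{Trace}
#' @export
getTrace <- function(x, channel, sweep = 1L) {
  stopifnot(is(x, "SweepSet"))
  Trace(x@data[, channel, sweep], rate = x@rate, clampMode = "current")
}

setMethod("show", "SweepSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("SweepSet: %d cells x %d sweeps, %d samples @ %g kHz\n",
              d[2L], d[3L], d[1L], object@rate / 1000))
  if (!is.null(object@groundTruth))
    cat(sprintf("  ground truth: %d true edges\n",
                sum(object@groundTruth@adjacency)))
})

#' @describeIn GroundTruthNetwork directed adjacency matrix
#' @param object a \linkS4class{GroundTruthNetwork}
#' @export
setMethod("adjacency", "GroundTruthNetwork", function(object) object@adjacency)

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf("GroundTruthNetwork: %d cells, %d directed edges\n",
              nrow(object@adjacency), sum(object@adjacency)))
})

#' @describeIn SessionPlan session table (n_new, n_old per session)
#' @param object a \linkS4class{SessionPlan}
#' @export
setMethod("sessions", "SessionPlan", function(object) object@sessions)

#' @describeIn SessionPlan available pipette count
#' @export
setMethod("nPipettes", "SessionPlan", function(object) object@nPipettes)

setMethod("show", "SessionPlan", function(object) {
  s <- object@sessions
  cat(sprintf("SessionPlan: %d sessions, %d pipettes\n", nrow(s),
              object@nPipettes))
  for (k in seq_len(nrow(s)))
    cat(sprintf("  session %d: %d new, %d maintained\n", k, s$n_new[k],
                s$n_old[k]))
})

#' @describeIn RigidTransform rotation matrix
#' @param object a \linkS4class{RigidTransform}
#' @export
setMethod("rotation", "RigidTransform", function(object) object@rotation)

#' @describeIn RigidTransform translation vector (um)
#' @export
setMethod("translation", "RigidTransform", function(object) object@translation)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (manipulator -> microscope)\n")
  cat(sprintf("  residual RMS: %.3g um\n", object@rms))
  cat(sprintf("  translation: [%.2f, %.2f, %.2f] um\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
})

#' @describeIn ConnectivityResult directed tested mask
#' @param object a \linkS4class{ConnectivityResult}
#' @export
setMethod("testedMask", "ConnectivityResult", function(object) object@tested)

#' @describeIn ConnectivityResult directed connected mask
#' @export
setMethod("connectedMask", "ConnectivityResult", function(object) object@connected)

setMethod("show", "ConnectivityResult", function(object) {
  cat(sprintf("ConnectivityResult: %d cells, %d found / %d tested connections\n",
              length(object@cellIds), sum(object@connected),
              sum(object@tested)))
})
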