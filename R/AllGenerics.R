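#' @import methods
NULL

#' Generic accessors for multipatch containers
#'
#' Small accessor generics shared by the container classes: traces, sweep
#' sets, session plans, rigid transforms and connectivity results.
#'
#' @param object an object of one of the package's S4 classes.
#' @param ... passed to methods.
#' @return The requested component; see the class documentation.
#' @name multipatch-generics
#' @keywords internal
NULL

#' @rdname multipatch-generics
#' @export
setGeneric("traceSamples", function(object, ...) standardGeneric("traceSamples"))

#' @rdname multipatch-generics
#' @export
setGeneric("sampleRate", function(object, ...) standardGeneric("sampleRate"))

#' @rdname multipatch-generics
#' @export
setGeneric("clampMode", function(object, ...) standardGeneric("clampMode"))

#' @rdname multipatch-generics
#' @export
setGeneric("nSweeps", function(object, ...) standardGeneric("nSweeps"))

#' @rdname multipatch-generics
#' @export
setGeneric("nChannels", function(object, ...) standardGeneric("nChannels"))

#' @rdname multipatch-generics
#' @export
setGeneric("groundTruth", function(object, ...) standardGeneric("groundTruth"))

#' @rdname multipatch-generics
#' @export
setGeneric("adjacency", function(object, ...) standardGeneric("adjacency"))

#' @rdname multipatch-generics
#' @export
setGeneric("testedMask", function(object, ...) standardGeneric("testedMask"))

#' @rdname multipatch-generics
#' @export
setGeneric("connectedMask", function(object, ...) standardGeneric("connectedMask"))

#' @rdname multipatch-generics
#' @export
setGeneric("sessions", function(object, ...) standardGeneric("sessions"))

#' @rdname multipatch-generics
#' @export
setGeneric("nPipettes", function(object, ...) standardGeneric("nPipettes"))

#' @rdname multipatch-generics
#' @export
setGeneric("rotation", function(object, ...) standardGeneric("rotation"))

#' @rdname multipatch-generics
#' @export
setGeneric("translation", function(object, ...) standardGeneric("translation"))
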