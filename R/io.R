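#' Write / read a sweep-set container
#'
#' A portable plain-text hierarchical container: a directory holding
#' \code{manifest.json} (format version, seed, rate, dimensions),
#' \code{protocol.json}, optional \code{ground_truth.json}, and one CSV per
#' sweep under \code{sweeps/} (one column per channel). Samples are written
#' with 17 significant digits so the write/read round trip is bit-exact.
#'
#' @param sweeps a \linkS4class{SweepSet}.
#' @param path container directory (created, must not exist or be empty).
#' @return \code{writeContainer} returns \code{path} invisibly;
#'   \code{readContainer} returns a \linkS4class{SweepSet}.
#' @export
writeContainer <- function(sweeps, path) {
  stopifnot(is(sweeps, "SweepSet"))
  dir.create(file.path(path, "sweeps"), recursive = TRUE, showWarnings = FALSE)
  d <- dim(sweeps@data)
  manifest <- list(format = "multipatch-sweepset", version = 1L,
                   seed = sweeps@seed, rate = sweeps@rate,
                   n_samples = d[1L], n_channels = d[2L], n_sweeps = d[3L],
                   has_ground_truth = !is.null(sweeps@groundTruth))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(sweeps@protocol, file.path(path, "protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  gt <- sweeps@groundTruth
  if (!is.null(gt)) {
    jsonlite::write_json(list(
      adjacency = gt@adjacency, amplitude = gt@amplitude,
      latency = gt@latency, rise = gt@rise, decay = gt@decay,
      trial_cv = gt@trialCV, positions = gt@positions),
      file.path(path, "ground_truth.json"), digits = NA, matrix = "rowmajor")
  }
  hdr <- paste(sprintf("ch%d", seq_len(d[2L])), collapse = ",")
  for (sw in seq_len(d[3L])) {
    m <- sweeps@data[, , sw, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = d[2L])
    lines <- c(hdr, do.call(paste, c(lapply(seq_len(d[2L]), function(j)
      sprintf("%.17g", m[, j])), sep = ",")))
    writeLines(lines, file.path(path, "sweeps",
                                sprintf("sweep_%03d.csv", sw)))
  }
  invisible(path)
}

#' @rdname writeContainer
#' @export
readContainer <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("manifest.json not found", call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(mf$version) || mf$version != 1L)
    stop(sprintf("unsupported-version: container version %s",
                 mf$version), call. = FALSE)
  proto <- jsonlite::read_json(file.path(path, "protocol.json"),
                               simplifyVector = TRUE)
  dat <- array(NA_real_, dim = c(mf$n_samples, mf$n_channels, mf$n_sweeps))
  for (sw in seq_len(mf$n_sweeps)) {
    f <- file.path(path, "sweeps", sprintf("sweep_%03d.csv", sw))
    if (!file.exists(f))
      stop(sprintf("integrity-error: missing sweep group 'sweep_%03d'", sw),
           call. = FALSE)
    m <- as.matrix(utils::read.csv(f))
    if (nrow(m) != mf$n_samples || ncol(m) != mf$n_channels)
      stop(sprintf("integrity-error: sweep group 'sweep_%03d' is truncated",
                   sw), call. = FALSE)
    dat[, , sw] <- m
  }
  gt <- NULL
  if (isTRUE(mf$has_ground_truth)) {
    g <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                             simplifyVector = TRUE)
    gt <- new("GroundTruthNetwork",
              adjacency = matrix(as.logical(g$adjacency),
                                 nrow = nrow(g$adjacency)),
              amplitude = g$amplitude, latency = g$latency,
              rise = g$rise, decay = g$decay, trialCV = g$trial_cv,
              positions = g$positions)
  }
  if (is.list(proto$spike_times_s))
    proto$spike_times_s <- lapply(proto$spike_times_s, as.numeric)
  new("SweepSet", data = dat, rate = as.numeric(mf$rate), protocol = proto,
      seed = as.integer(mf$seed), groundTruth = gt)
}

#' Export a connectivity result
#'
#' \code{"edge_csv"}: one row per tested ordered pair (pre_id, post_id,
#' sessions, connected, amplitude_mV, latency_ms, distance_um), sorted by
#' cell id. \code{"adjacency_json"}: cells plus dense tested/connected/
#' amplitude/latency matrices. \code{"graph_ml"}: GraphML via igraph, edges
#' being the found connections.
#'
#' @param result a \linkS4class{ConnectivityResult}.
#' @param path output file.
#' @param format one of \code{"edge_csv"}, \code{"adjacency_json"},
#'   \code{"graph_ml"}.
#' @return \code{path}, invisibly.
#' @export
exportGraph <- function(result, path, format = c("edge_csv",
                        "adjacency_json", "graph_ml")) {
  stopifnot(is(result, "ConnectivityResult"))
  format <- match.arg(format)
  ids <- result@cellIds
  if (format == "edge_csv") {
    idx <- which(result@tested, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    df <- data.frame(
      pre_id = ids[idx[, 1L]], post_id = ids[idx[, 2L]],
      pre_session = sub("^.*\\.", "", ids[idx[, 1L]]),
      post_session = sub("^.*\\.", "", ids[idx[, 2L]]),
      tested = rep(TRUE, nrow(idx)),
      connected = result@connected[idx],
      amplitude_mV = result@amplitude[idx],
      latency_ms = result@latency[idx],
      distance_um = result@distances[idx])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "adjacency_json") {
    jsonlite::write_json(list(
      cells = ids, tested = result@tested, connected = result@connected,
      amplitude_mV = result@amplitude, latency_ms = result@latency,
      distance_um = result@distances),
      path, digits = NA, matrix = "rowmajor", na = "null")
  } else {
    g <- igraph::graph_from_adjacency_matrix(
      result@connected * 1, mode = "directed")
    igraph::V(g)$name <- ids
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an adjacency_json export
#'
#' @param path file written by \code{\link{exportGraph}} with format
#'   \code{"adjacency_json"}.
#' @return list: \code{cells}, \code{tested}, \code{connected},
#'   \code{amplitude_mV}, \code{latency_ms} (matrices).
#' @export
importAdjacency <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(x$cells)
  list(cells = x$cells,
       tested = matrix(as.logical(x$tested), n, n,
                       dimnames = list(x$cells, x$cells)),
       connected = matrix(as.logical(x$connected), n, n,
                          dimnames = list(x$cells, x$cells)),
       amplitude_mV = matrix(as.numeric(x$amplitude_mV), n, n),
       latency_ms = matrix(as.numeric(x$latency_ms), n, n))
}

#' Write a single trace as CSV
#'
#' Columns \code{t_s} and \code{value} (mV or pA); full precision.
#'
#' @param trace a \linkS4class{Trace}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  t_s <- time(trace)
  writeLines(c("t_s,value",
               sprintf("%.17g,%.17g", t_s, traceSamples(trace))), path)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @param rate,clampMode trace metadata (CSV stores only samples).
#' @export
readTraceCsv <- function(path, rate = 20000, clampMode = "current") {
  df <- utils::read.csv(path)
  Trace(df$value, rate = rate, clampMode = clampMode,
        t0 = if ("t_s" %in% names(df)) df$t_s[1L] else 0)
}
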