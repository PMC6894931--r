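#' Run the full synthetic screening pipeline from a configuration
#'
#' Executes generate -> feature extraction -> connection screening ->
#' statistics end to end. The configuration (a YAML file or an equivalent
#' nested list) must carry a \code{seed}; every random draw derives from
#' it, so identical configurations produce identical artifacts. Artifacts
#' written to \code{out_dir}: \code{cells.csv} (per-cell properties + QC),
#' \code{edges.csv}, \code{adjacency.json}, \code{stats.json} and a
#' JSON-lines \code{log.jsonl} (timestamps live only in the log, keeping
#' the data artifacts byte-reproducible).
#'
#' @param config path to a YAML file, or a list. Sections:
#'   \code{seed} (required); \code{synth} (n_cells, p_conn, n_sweeps,
#'   noise_sd_mv, ...); \code{detect} (k_sd, smooth_ms, ...);
#'   \code{qc} (rmp_cutoff_mv, ra_cutoff_mohm).
#' @param out_dir output directory (created). NULL runs in a temporary
#'   directory.
#' @return invisibly, a list with the main objects: \code{sweeps},
#'   \code{cells}, \code{calls}, \code{result}, \code{stats},
#'   \code{out_dir}.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config-error: no such config file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config-error: config must be a list or YAML path",
                             call. = FALSE)
  missing <- setdiff("seed", names(config))
  if (length(missing))
    stop(sprintf("config-error: missing required field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (is.null(out_dir)) out_dir <- tempfile("multipatch_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  logln <- function(...) {
    cat(jsonlite::toJSON(c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                           list(...)), auto_unbox = TRUE, digits = NA),
        "\n", file = log_path, append = TRUE)
  }
  sy <- config$synth %||% list()
  de <- config$detect %||% list()
  qc <- config$qc %||% list()
  logln(event = "start", seed = config$seed,
        version = as.character(utils::packageVersion("multipatch")),
        config_hash = .configHash(config))

  sweeps <- do.call(synthCluster, c(
    list(n_cells = sy$n_cells %||% 8L, p_conn = sy$p_conn %||% 0.15,
         n_sweeps = sy$n_sweeps %||% 40L,
         noise_sd_mv = sy$noise_sd_mv %||% 0.2,
         seed = config$seed),
    sy[setdiff(names(sy), c("n_cells", "p_conn", "n_sweeps", "noise_sd_mv"))]))
  logln(event = "synth", n_cells = nChannels(sweeps),
        n_sweeps = nSweeps(sweeps))

  nc <- nChannels(sweeps)
  cells <- do.call(rbind, lapply(seq_len(nc), function(ch) {
    avg <- averageSweeps(sweeps, ch)
    rmp <- restingPotential(avg)
    tp <- vcTestPulse(seed = config$seed + ch)
    rr <- measureResistances(tp$trace, onset_s = tp$onset_s,
                             width_s = tp$width_s)
    spk <- detectSpikes(avg)
    feat <- if (length(spk) >= 2L) apFeatures(avg, spk[2L]) else
      if (length(spk) >= 1L) apFeatures(avg, spk[1L]) else NULL
    data.frame(cell_id = sprintf("%d.1", ch), session = 1L, pipette = ch,
               rmp_mV = rmp, ra_MOhm = rr$ra_mohm, rin_MOhm = rr$rin_mohm,
               ap_threshold_mV = feat$threshold_mv %||% NA_real_,
               ap_amplitude_mV = feat$amplitude_mv %||% NA_real_,
               ap_halfwidth_ms = feat$half_width_ms %||% NA_real_)
  }))
  cells <- qcFilter(cells,
                    rmp_cutoff_mv = qc$rmp_cutoff_mv %||% -60,
                    ra_cutoff_mohm = qc$ra_cutoff_mohm %||% 40)
  logln(event = "features", included = sum(cells$included),
        rmp_cutoff_mv = qc$rmp_cutoff_mv %||% -60,
        ra_cutoff_mohm = qc$ra_cutoff_mohm %||% 40)

  k_sd <- de$k_sd %||% 3
  det_args <- list(sweeps, k_sd = k_sd)
  if (!is.null(de$smooth_ms)) det_args$smooth_ms <- de$smooth_ms
  if (!is.null(k_sd) && k_sd <= 0) {
    warning("degenerate threshold: k_sd <= 0 calls every tested pair connected")
    det_args$latency_gate_ms <- c(-Inf, Inf)
  }
  calls <- do.call(detectConnections, det_args)
  logln(event = "detect", k_sd = k_sd, found = sum(calls$connected),
        tested = nrow(calls))

  plan <- SessionPlan(list(c(nc, 0)), nPipettes = nc)
  result <- buildConnectivity(calls, plan,
                              positions = groundTruth(sweeps)@positions)
  statsOut <- list(
    found = sum(result@connected), tested = sum(result@tested),
    connection_probability = connectionProbability(
      sum(result@connected), sum(result@tested)),
    distances = distanceSummary(result@distances[result@tested]),
    thresholds = list(k_sd = k_sd,
                      rmp_cutoff_mv = qc$rmp_cutoff_mv %||% -60,
                      ra_cutoff_mohm = qc$ra_cutoff_mohm %||% 40))

  utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  exportGraph(result, file.path(out_dir, "edges.csv"), "edge_csv")
  exportGraph(result, file.path(out_dir, "adjacency.json"), "adjacency_json")
  jsonlite::write_json(statsOut, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  logln(event = "done")
  invisible(list(sweeps = sweeps, cells = cells, calls = calls,
                 result = result, stats = statsOut, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# polynomial rolling hash over the canonical JSON serialisation of the config
.configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
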