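#' Directed connections testable in a simultaneously recorded cluster
#'
#' With n cells recorded simultaneously every ordered (pre, post) pair can be
#' probed, so the tested-connection count scales as c = n(n-1).
#'
#' @param n number of simultaneously recorded cells (non-negative integer).
#' @return integer count of ordered pairs.
#' @examples
#' pairsTotal(8)   # 56
#' pairsTotal(10)  # 90
#' @export
pairsTotal <- function(n) {
  .checkCount(n, "n")
  as.integer(n) * (as.integer(n) - 1L)
}

#' Additional connections gained by a clean-to-extend session
#'
#' When n_new fresh cells are patched while n_old cells are maintained from
#' earlier sessions, the newly testable directed pairs number
#' c_new = 2 n_new n_old + n_new (n_new - 1): both orientations between every
#' new/old pair, plus all ordered pairs among the new cells. Old/old pairs
#' were already tested and are not recounted.
#'
#' @param n_new newly patched cell count.
#' @param n_old maintained cell count.
#' @return integer count of newly tested ordered pairs.
#' @examples
#' pairsExtension(4, 4)  # 44
#' pairsExtension(5, 3)  # 50
#' @export
pairsExtension <- function(n_new, n_old) {
  .checkCount(n_new, "n_new")
  .checkCount(n_old, "n_old")
  n_new <- as.integer(n_new); n_old <- as.integer(n_old)
  2L * n_new * n_old + n_new * (n_new - 1L)
}

.checkCount <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  invisible(TRUE)
}

#' Summarise a session plan: cells, tested connections, tested mask
#'
#' Accumulates the directed tested-pair mask over a clean-to-complete /
#' clean-to-extend experiment. The first session contributes n(n-1) pairs;
#' each later session contributes \code{\link{pairsExtension}} pairs between
#' its new cells and the maintained cells plus among the new cells. Cells are
#' labelled \code{"<cellIndex>.<sessionIndex>"}. Maintained cells are taken
#' to be the most recently patched ones.
#'
#' @param plan a \linkS4class{SessionPlan}.
#' @return list with \code{total_cells}, \code{total_tested},
#'   \code{per_session} (data.frame with a \code{tested} column), and
#'   \code{tested_mask}, a directed logical matrix over session-qualified
#'   cell ids with \code{sum(tested_mask) == total_tested}.
#' @examples
#' plan <- SessionPlan(list(c(8, 0), c(4, 4), c(5, 3)), nPipettes = 8)
#' planSummary(plan)[c("total_cells", "total_tested")]
#' @export
planSummary <- function(plan) {
  stopifnot(is(plan, "SessionPlan"))
  validObject(plan)
  s <- sessions(plan)
  total_cells <- sum(s$n_new)
  ids <- unlist(lapply(seq_len(nrow(s)), function(k) {
    if (s$n_new[k] == 0L) return(character())
    first <- if (k == 1L) 1L else sum(s$n_new[seq_len(k - 1L)]) + 1L
    sprintf("%d.%d", seq.int(first, length.out = s$n_new[k]), k)
  }))
  mask <- matrix(FALSE, total_cells, total_cells, dimnames = list(ids, ids))
  tested_per <- integer(nrow(s))
  recorded <- integer(0)       # indices of all cells patched so far
  for (k in seq_len(nrow(s))) {
    first <- if (k == 1L) 1L else sum(s$n_new[seq_len(k - 1L)]) + 1L
    new_idx <- if (s$n_new[k] > 0L) seq.int(first, length.out = s$n_new[k])
               else integer(0)
    # maintained cells: the most recently patched n_old of the prior cells
    old_idx <- if (s$n_old[k] > 0L) utils::tail(recorded, s$n_old[k])
               else integer(0)
    grp <- c(old_idx, new_idx)
    before <- sum(mask)
    for (i in grp) for (j in grp) {
      if (i != j && (i %in% new_idx || j %in% new_idx)) mask[i, j] <- TRUE
    }
    tested_per[k] <- sum(mask) - before
    recorded <- c(recorded, new_idx)
  }
  list(total_cells = total_cells, total_tested = sum(mask),
       per_session = cbind(s, tested = tested_per), tested_mask = mask)
}

#' Success rate of a multipatch configuration
#'
#' Ratio of successfully recorded cells to the maximum number of pipettes,
#' as an integer percent (the raw ratio is returned alongside).
#'
#' @param mean_cells average recorded cluster size.
#' @param n_pipettes available pipette count.
#' @return list with \code{percent} (integer) and \code{ratio}.
#' @examples
#' successRate(5.3, 6)$percent   # 88
#' successRate(9.2, 10)$percent  # 92
#' @export
successRate <- function(mean_cells, n_pipettes) {
  if (n_pipettes <= 0) stop("n_pipettes must be positive", call. = FALSE)
  if (mean_cells < 0 || mean_cells > n_pipettes)
    stop("mean_cells must lie in [0, n_pipettes]", call. = FALSE)
  ratio <- mean_cells / n_pipettes
  list(percent = as.integer(round(100 * ratio)), ratio = ratio)
}

#' Monte-Carlo yield of a multipatch experiment with and without cleaning
#'
#' Stochastic model of cluster assembly: pipettes attempt patches one after
#' another; each attempt succeeds with probability \code{p_patch}, and every
#' already-established recording is lost with probability
#' \code{p_loss_per_patch} during each subsequent attempt. With
#' \code{cleaning = TRUE} a failed pipette is cleaned and retries (on a fresh
#' neighbouring cell) up to \code{max_retries} times — the clean-to-complete
#' strategy. \code{extend_rounds} additional clean-to-extend sessions keep
#' the established cells and re-patch the remaining pipettes, accumulating
#' tested pairs via \code{\link{pairsExtension}}.
#'
#' @param n_pipettes pipette count.
#' @param p_patch per-attempt probability of establishing a recording.
#' @param p_loss_per_patch per-attempt hazard of losing each established
#'   recording.
#' @param cleaning logical; retry failed pipettes after cleaning.
#' @param max_retries retries per pipette when cleaning.
#' @param extend_rounds clean-to-extend sessions after the initial cluster.
#' @param n_rep Monte-Carlo repetitions.
#' @param seed integer seed (deterministic output for a fixed seed).
#' @return list: \code{cluster_sizes} (per repetition, initial cluster),
#'   \code{mean_cluster_size}, \code{success_rate_pct} (integer percent),
#'   \code{tested_connections} (per repetition, incl. extensions),
#'   \code{mean_tested}.
#' @examples
#' simulateYield(8, p_patch = 0.9, p_loss_per_patch = 0.01, cleaning = TRUE,
#'               n_rep = 100, seed = 1)$mean_cluster_size
#' @export
simulateYield <- function(n_pipettes, p_patch, p_loss_per_patch = 0,
                          cleaning = FALSE, max_retries = 2L,
                          extend_rounds = 0L, n_rep = 1000L, seed = 1L) {
  stopifnot(n_pipettes >= 1, p_patch >= 0, p_patch <= 1,
            p_loss_per_patch >= 0, p_loss_per_patch <= 1, n_rep >= 1)
  rng <- .childRNG(seed, "yield")
  sizes <- integer(n_rep)
  tested <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    est <- 0L
    for (p in seq_len(n_pipettes)) {
      attempts <- if (cleaning) 1L + max_retries else 1L
      for (a in seq_len(attempts)) {
        if (est > 0L && p_loss_per_patch > 0)
          est <- stats::rbinom(1L, est, 1 - p_loss_per_patch)
        if (stats::runif(1L) < p_patch) { est <- est + 1L; break }
      }
    }
    sizes[r] <- est
    tot <- pairsTotal(est)
    if (extend_rounds > 0L) {
      held <- est
      for (k in seq_len(extend_rounds)) {
        n_old <- min(held, n_pipettes - 1L)
        n_free <- n_pipettes - n_old
        got <- 0L
        for (p in seq_len(n_free)) {
          attempts <- if (cleaning) 1L + max_retries else 1L
          for (a in seq_len(attempts)) {
            alive <- n_old + got
            if (alive > 0L && p_loss_per_patch > 0) {
              lost <- alive - stats::rbinom(1L, alive, 1 - p_loss_per_patch)
              # losses hit old and new alike; attribute to old first
              drop_old <- min(lost, n_old); n_old <- n_old - drop_old
              got <- got - (lost - drop_old)
            }
            if (stats::runif(1L) < p_patch) { got <- got + 1L; break }
          }
        }
        tot <- tot + pairsExtension(got, n_old)
        held <- n_old + got
      }
    }
    tested[r] <- tot
  }
  .restoreRNG(rng)
  list(cluster_sizes = sizes,
       mean_cluster_size = mean(sizes),
       success_rate_pct = successRate(mean(sizes), n_pipettes)$percent,
       tested_connections = tested,
       mean_tested = mean(tested))
}

#' Read / write session plans as JSON
#'
#' JSON schema: \code{{"n_pipettes": int,
#' "sessions": [{"n_new": int, "n_old": int}, ...]}}.
#'
#' @param path file path.
#' @param plan a \linkS4class{SessionPlan}.
#' @return \code{readSessionPlan} returns a \linkS4class{SessionPlan};
#'   \code{writeSessionPlan} returns \code{path} invisibly.
#' @export
readSessionPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  SessionPlan(as.data.frame(x$sessions), nPipettes = x$n_pipettes)
}

#' @rdname readSessionPlan
#' @export
writeSessionPlan <- function(plan, path) {
  stopifnot(is(plan, "SessionPlan"))
  jsonlite::write_json(
    list(n_pipettes = nPipettes(plan),
         sessions = sessions(plan)[, c("n_new", "n_old")]),
    path, auto_unbox = TRUE)
  invisible(path)
}

# Seeded child RNG streams: save the caller's RNG state, reseed from a
# deterministic hash of (seed, label), and restore on exit via .restoreRNG.
.childRNG <- function(seed, label) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  set.seed((as.integer(seed) * 10007L + h) %% 2147483647L)
  old
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
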