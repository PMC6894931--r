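#' Connection probability
#'
#' Found over tested directed connections.
#'
#' @param found connections found.
#' @param tested connections tested (> 0).
#' @return proportion.
#' @examples
#' connectionProbability(38, 150)   # three-session example accounting
#' @export
connectionProbability <- function(found, tested) {
  if (tested <= 0) stop("undefined-proportion: tested must be > 0",
                        call. = FALSE)
  if (found < 0 || found > tested)
    stop("found must lie in [0, tested]", call. = FALSE)
  found / tested
}

#' Wald confidence interval for a difference of connection probabilities
#'
#' Simple asymptotic interval without continuity correction:
#' (p1 - p2) +/- z sqrt(p1(1-p1)/n1 + p2(1-p2)/n2), with z the
#' standard-normal quantile at (1 + level)/2.
#'
#' @param found1,tested1 counts of group 1.
#' @param found2,tested2 counts of group 2.
#' @param level confidence level (default 0.90).
#' @return list: \code{p1}, \code{p2}, \code{diff}, \code{se}, \code{z},
#'   \code{ci} (lo, hi), \code{level}.
#' @examples
#' waldCiDiff(20, 100, 10, 100)$ci   # [0.01776, 0.18224]
#' @export
waldCiDiff <- function(found1, tested1, found2, tested2, level = 0.90) {
  stopifnot(tested1 > 0, tested2 > 0, level > 0, level < 1)
  p1 <- found1 / tested1; p2 <- found2 / tested2
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(p1 * (1 - p1) / tested1 + p2 * (1 - p2) / tested2)
  d <- p1 - p2
  list(p1 = p1, p2 = p2, diff = d, se = se, z = z,
       ci = c(d - z * se, d + z * se), level = level)
}

#' Two-sided Fisher's exact test for a 2x2 table of counts
#'
#' Exact p by summing, over all tables with the observed margins, the
#' hypergeometric probabilities not exceeding that of the observed table
#' (probability-mass ordering, the common two-sided convention).
#'
#' @param found1,tested1 counts of group 1.
#' @param found2,tested2 counts of group 2.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisherExact(3, 4, 1, 4)   # 0.4857...
#' @export
fisherExact <- function(found1, tested1, found2, tested2) {
  stopifnot(found1 >= 0, found2 >= 0, found1 <= tested1, found2 <= tested2)
  if (tested1 == 0 || tested2 == 0)
    stop("invalid-table: empty margin", call. = FALSE)
  m <- found1 + found2                      # total successes
  k <- seq(max(0, m - tested2), min(tested1, m))
  pk <- stats::dhyper(k, tested1, tested2, m)
  p_obs <- stats::dhyper(found1, tested1, tested2, m)
  # tolerance guards against ties broken by floating-point noise
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

#' Equivalence report on relative differences (TOST via the 90 percent CI)
#'
#' For paired data the per-pair relative difference 100 (after - before) /
#' before is summarised by its mean and a t-based confidence interval; for
#' unpaired groups the relative difference of the group means is used with
#' a delta-method standard error. Equivalence at alpha = 0.05 is declared
#' when the 90 percent CI lies entirely within +/- \code{bound_pct}
#' (the standard TOST/CI duality).
#'
#' @param before,after numeric vectors (equal length when paired).
#' @param paired logical.
#' @param bound_pct equivalence bound in percent (20 for cellular and AP
#'   properties, 25 for spontaneous EPSP properties, by the conventions
#'   this package follows).
#' @param level confidence level (default 0.90).
#' @return list: \code{mean_rel_diff_pct}, \code{ci_pct}, \code{bound_pct},
#'   \code{equivalent}, \code{paired}, \code{n}.
#' @export
equivalenceReport <- function(before, after, paired = TRUE, bound_pct = 20,
                              level = 0.90) {
  stopifnot(level > 0, level < 1)
  if (paired) {
    if (length(before) != length(after))
      stop("paired data must have equal lengths", call. = FALSE)
    if (any(before == 0))
      stop("undefined-relative-difference: zero baseline value",
           call. = FALSE)
    rel <- 100 * (after - before) / before
    n <- length(rel)
    m <- mean(rel); se <- stats::sd(rel) / sqrt(n)
    tq <- stats::qt((1 + level) / 2, df = n - 1L)
    ci <- c(m - tq * se, m + tq * se)
  } else {
    ma <- mean(after); mb <- mean(before)
    if (mb == 0)
      stop("undefined-relative-difference: zero baseline mean", call. = FALSE)
    na <- length(after); nb <- length(before)
    va <- stats::var(after) / na; vb <- stats::var(before) / nb
    m <- 100 * (ma - mb) / mb
    se <- 100 * sqrt(va / mb^2 + ma^2 * vb / mb^4)
    df <- (va / mb^2 + ma^2 * vb / mb^4)^2 /
      ((va / mb^2)^2 / (na - 1L) + (ma^2 * vb / mb^4)^2 / (nb - 1L))
    tq <- stats::qt((1 + level) / 2, df = df)
    ci <- c(m - tq * se, m + tq * se)
    n <- c(before = nb, after = na)
  }
  list(mean_rel_diff_pct = m, ci_pct = ci, bound_pct = bound_pct,
       equivalent = ci[1L] >= -bound_pct && ci[2L] <= bound_pct,
       paired = paired, level = level, n = n)
}

#' Rank tests for group differences
#'
#' Mann-Whitney U (unpaired) or Wilcoxon signed-rank (paired), exact for
#' small samples (n <= 10) and normal-approximated beyond.
#'
#' @param group_a,group_b numeric vectors (equal length when paired).
#' @param paired logical.
#' @return two-sided p-value.
#' @export
rankTests <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("need at least 3 observations per group", call. = FALSE)
  if (paired && all(group_a == group_b))
    stop("undefined-test: all differences are ties", call. = FALSE)
  # exact enumeration only for small tie-free samples; normal approximation
  # otherwise (ties preclude the exact null distribution)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && max(length(group_a), length(group_b)) <= 10L
  stats::wilcox.test(group_a, group_b, paired = paired, exact = exact,
                     correct = !exact)$p.value
}

#' Per-round summary of intersomatic distances
#'
#' Median, quartiles and count of pairwise intersomatic distances for each
#' recording round; empty rounds are dropped with a warning.
#'
#' @param distances_um numeric distances (um, >= 0).
#' @param round_index recording-round index per distance.
#' @return data.frame: round, n, median_um, q25_um, q75_um.
#' @export
distanceSummary <- function(distances_um, round_index = rep(1L,
                            length(distances_um))) {
  stopifnot(all(distances_um >= 0), length(distances_um) ==
            length(round_index))
  rounds <- sort(unique(round_index))
  out <- lapply(rounds, function(r) {
    d <- distances_um[round_index == r]
    if (!length(d)) { warning(sprintf("round %s is empty; omitted", r))
                      return(NULL) }
    data.frame(round = r, n = length(d), median_um = stats::median(d),
               q25_um = unname(stats::quantile(d, 0.25)),
               q75_um = unname(stats::quantile(d, 0.75)))
  })
  do.call(rbind, out)
}

#' Repeated-measures ANOVA convenience wrapper
#'
#' Delegates to \code{stats::aov} with an Error(subject) stratum; used for
#' comparing a property across repeated cleaning rounds on the same cells.
#'
#' @param value numeric response.
#' @param round factor-like round labels.
#' @param subject factor-like subject (cell) ids.
#' @return p-value for the round effect.
#' @export
repeatedAnova <- function(value, round, subject) {
  d <- data.frame(value = value, round = factor(round),
                  subject = factor(subject))
  fit <- stats::aov(value ~ round + Error(subject / round), data = d)
  s <- summary(fit)
  tab <- s[["Error: subject:round"]][[1L]]
  tab[["Pr(>F)"]][1L]
}
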