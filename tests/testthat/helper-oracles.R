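# Independent oracles used across the suite. These re-derive expected values
# by brute force / enumeration and stay independent of the package internals
# they check.

# ordered-pair enumeration for a session plan: simulate the experiment by
# explicitly listing cells and marking every ordered pair recorded together
# for the first time in each session
enumeratePlanTested <- function(sessions) {
  cells <- character(0)
  tested <- character(0)          # "i->j" strings
  for (k in seq_len(nrow(sessions))) {
    n_new <- sessions$n_new[k]; n_old <- sessions$n_old[k]
    new_cells <- if (n_new > 0)
      paste0("c", length(cells) + seq_len(n_new)) else character(0)
    old_cells <- if (n_old > 0) utils::tail(cells, n_old) else character(0)
    grp <- c(old_cells, new_cells)
    for (a in grp) for (b in grp) {
      if (a != b) {
        key <- paste(a, b, sep = "->")
        if (!key %in% tested) tested <- c(tested, key)
      }
    }
    cells <- c(cells, new_cells)
  }
  list(n_cells = length(cells), n_tested = length(tested))
}

# exact distribution of the final cluster size for the sequential-patching
# yield model: per pipette up to `attempts` tries, each try first thins the
# established count binomially (loss hazard q), then succeeds w.p. p
yieldSizeDist <- function(n_pip, p, q, attempts) {
  dist <- c(1, rep(0, n_pip))      # P(established = 0..n_pip)
  for (pip in seq_len(n_pip)) {
    done <- rep(0, n_pip + 1)
    cont <- dist
    for (a in seq_len(attempts)) {
      thinned <- rep(0, n_pip + 1)
      for (e in 0:n_pip) if (cont[e + 1] > 0)
        for (k in 0:e)
          thinned[k + 1] <- thinned[k + 1] +
            cont[e + 1] * stats::dbinom(k, e, 1 - q)
      # success: established k -> k+1, pipette finished
      for (k in 0:(n_pip - 1))
        done[k + 2] <- done[k + 2] + thinned[k + 1] * p
      cont <- thinned * (1 - p)
    }
    dist <- done + cont
  }
  dist
}

# brute-force per-offset least-squares fit of template to data (oracle for
# the sliding template-scaling criterion)
olsCriterionAt <- function(y, tmpl, offset) {
  seg <- y[offset:(offset + length(tmpl) - 1L)]
  fit <- stats::lm.fit(cbind(1, tmpl), seg)
  sse <- sum(fit$residuals^2)
  se <- sqrt(sse / (length(tmpl) - 1L))
  list(scale = unname(fit$coefficients[2L]),
       criterion = unname(fit$coefficients[2L]) / se)
}

# random proper rotation (QR of a Gaussian matrix, sign-corrected)
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# match detected event times to ground truth within a tolerance (s)
matchEvents <- function(true_t, det_t, tol = 0.005) {
  recall <- if (length(true_t))
    mean(vapply(true_t, function(t) any(abs(det_t - t) < tol), logical(1)))
  else NA_real_
  fp <- sum(vapply(det_t, function(t) all(abs(true_t - t) >= tol),
                   logical(1)))
  list(recall = recall, fp = fp)
}
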