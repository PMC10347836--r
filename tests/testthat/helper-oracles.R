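# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the RK4 integrator, rank-based correlation,
# hypergeometric tail and brute-force IDR scan are all written from first
# principles so agreement with the package is informative.

# classical fourth-order Runge-Kutta for dp/dt = alpha r(t) - kd p with r
# linearly interpolated between nodes; steps aligned to segment boundaries
rk4_protein <- function(p0, alpha, kd, times, values, steps_per_segment = 400) {
  interp <- function(t) {
    k <- findInterval(t, times, rightmost.closed = TRUE)
    k <- min(max(k, 1), length(times) - 1)
    w <- (t - times[k]) / (times[k + 1] - times[k])
    (1 - w) * values[k] + w * values[k + 1]
  }
  deriv <- function(t, p) alpha * interp(t) - kd * p
  out <- numeric(length(times))
  out[1] <- p <- p0
  for (k in seq_len(length(times) - 1)) {
    h <- (times[k + 1] - times[k]) / steps_per_segment
    t <- times[k]
    for (i in seq_len(steps_per_segment)) {
      k1 <- deriv(t, p)
      k2 <- deriv(t + h / 2, p + h / 2 * k1)
      k3 <- deriv(t + h / 2, p + h / 2 * k2)
      k4 <- deriv(t + h, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[k + 1] <- p
  }
  out
}

# Spearman correlation from the definition: Pearson on average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# equal-variance two-sample two-tailed t-test from the textbook formula
t_test_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# two-sided Fisher p by hypergeometric enumeration: sum of all table
# probabilities not exceeding the observed one
fisher_oracle <- function(k, nA, nB, N) {
  support <- max(0, nA + nB - N):min(nA, nB)
  probs <- dhyper(support, nB, N - nB, nA)
  p_obs <- dhyper(k, nB, N - nB, nA)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force IDR scan: test every substring for "all scores > cutoff",
# then keep maximal qualifying runs longer than min_len
idr_brute <- function(scores, cutoff = 0.5, min_len = 30) {
  n <- length(scores)
  hits <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(scores[s:e] > cutoff) &&
        (s == 1 || scores[s - 1] <= cutoff) &&
        (e == n || scores[e + 1] <= cutoff) &&
        (e - s + 1) > min_len) {
        hits[[length(hits) + 1]] <- c(s, e)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, hits)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

# small noise-free bundle configuration used by several recovery tests:
# no dropout and no batch shift unless a test plants them explicitly
quiet_config <- function(n_genes = 150, seed = 42, ...) {
  sim_config(
    n_genes = n_genes, noise_sd = 0,
    batch_offsets = c(batch1 = 0, batch2 = 0, batch3 = 0),
    detection_floor = 0, seed = seed, ...
  )
}

# stage-averaged tibble from a gene x stage matrix (test construction aid)
avg_tbl <- function(m, layer = NULL) {
  out <- tibble::as_tibble(m, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "stage", values_to = "value")
  out$stage <- factor(out$stage, levels = colnames(m))
  attr(out, "layer") <- layer
  out
}
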