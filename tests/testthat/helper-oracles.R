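# Independent brute-force oracles used to pin expected values.

# AUC by enumerating all (a_i, b_j) pairs, ties counted 1/2.
oracle_auc <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (y > x) + 0.5 * (y == x)
  tot / (length(a) * length(b))
}

# One-sided (greater) rank-sum p-value by enumerating every assignment of
# the pooled values to the two groups.  Assumes no ties across groups.
oracle_ranksum_greater <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  obs <- sum(rank(pooled)[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2L, function(idx) sum(rank(pooled)[idx]))
  mean(stats >= obs)
}

# Two-sided Wilcoxon signed-rank p by enumerating all sign patterns of the
# nonzero paired differences (no tied |d| assumed).
oracle_signed_rank_two_sided <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1L, function(s) sum(r[s]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Yekutieli adjustment from the step-up formula with the
# harmonic correction factor.
oracle_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))  # enforce monotone non-decreasing
  pmin(adj, 1)[order(o)]
}

# BDO matrix by looping over unit pairs and trials (ties and invalid
# entries excluded from the trial count).
oracle_bdo <- function(mu, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(mu), ncol(mu))
  n <- ncol(mu)
  bdo <- matrix(NA_real_, n, n)
  diag(bdo) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      later <- 0L; tot <- 0L
      for (k in seq_len(nrow(mu))) {
        if (!valid[k, i] || !valid[k, j]) next
        if (mu[k, i] == mu[k, j]) next
        tot <- tot + 1L
        if (mu[k, j] > mu[k, i]) later <- later + 1L
      }
      if (tot > 0L) bdo[i, j] <- 2 * later / tot - 1
    }
  }
  bdo
}

# Small synthetic session shared across tests.
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_trials = 30L, n_units = 12L, seed = 123L)
  defaults[names(args)] <- args
  do.call(session_config, defaults)
}
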