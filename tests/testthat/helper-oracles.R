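# Independent brute-force oracles, implemented from first principles and kept
# free of the code paths they check.

# Two-sided Fisher exact p for [[a,b],[c,d]] by exhaustive enumeration of all
# tables with the observed margins, using choose()-based probabilities:
# sum of probabilities of tables no more probable than the observed one
# (standard 1e-7 relative tolerance for floating-point ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  N <- r1 + r2
  xs <- max(0L, k - r2):min(k, r1)
  prob <- choose(r1, xs) * choose(r2, k - xs) / choose(N, k)
  p_obs <- choose(r1, a) * choose(r2, k - a) / choose(N, k)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Naive O(m^2) Benjamini-Hochberg step-up from the definition: with p sorted
# ascending, p_adj at sort position i = min over j >= i of m * p_(j) / j,
# capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  padj <- numeric(m)
  for (i in seq_len(m)) {
    padj[o[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  padj
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (no ties assumed). U = rank-sum statistic of x; two-sided p doubles the
# smaller tail, capped at 1.
oracle_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}
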