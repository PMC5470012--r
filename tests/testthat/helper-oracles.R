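# Independent brute-force oracles for the concordance statistics. These are
# deliberately naive (full enumeration, direct definitions) and share no code
# with the package implementations they check.

# Spearman as the Pearson correlation of midranks.
oracle_spearman <- function(a, b) {
  stats::cor(rank(a), rank(b))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the ranks of |d| (zeros dropped first).
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Exact two-sided rank-sum p by enumerating all choose(n, nx) assignments of
# the joint ranks to group x (tie-free inputs).
oracle_rank_sum <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  splits <- utils::combn(n, nx)
  w_all <- colSums(matrix(as.numeric(splits), nrow = nx))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
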