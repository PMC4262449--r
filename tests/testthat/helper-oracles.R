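# Independent brute-force oracles. These deliberately avoid the code paths
# they check: Spearman is recomputed as rank-then-Pearson from first
# principles, and the rank tests by exhaustive enumeration.

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exact paired signed-rank: enumerate all 2^n sign assignments on the ranks
# of |d| (zero differences removed), two-sided p by distance of V from its
# mean n(n+1)/4.
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  center <- n * (n + 1) / 4
  p <- mean(abs(v_all - center) >= abs(v_obs - center) - 1e-12)
  list(statistic = v_obs, p_value = p)
}

# Exact rank-sum: enumerate all C(n1+n2, n1) group labelings; statistic is
# Mann-Whitney U for group a; two-sided p by distance from the mean.
oracle_ranksum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  center <- n1 * n2 / 2
  p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-12)
  list(statistic = u_obs, p_value = p)
}

# Fisher combination reference by numeric integration of the chi-square
# density rather than the distribution function.
oracle_fisher_p <- function(ps) {
  x <- -2 * sum(log(ps))
  stats::integrate(function(t) stats::dchisq(t, df = 2 * length(ps)),
                   lower = x, upper = Inf, rel.tol = 1e-10)$value
}
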