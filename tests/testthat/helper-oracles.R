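# Independent oracles used by unit and acceptance tests.

# exhaustive-enumeration oracle for the exact Mann-Whitney two-sided p:
# every assignment of ranks to sample a is equally likely under H0
mw_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) sum(idx) - na * (na + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# quadratic-time step-up oracle: q_i = min over p_(j) >= p_i of m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
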