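# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the rank-sum oracle enumerates rank assignments with
# combn(); the Pearson oracle is the covariance/sigma closed form.

brute_force_rank_sum <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  assignments <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(assignments, 2, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  list(u = u_obs,
       p_less = p_less,
       p_greater = p_greater,
       p_two_sided = min(1, 2 * min(p_less, p_greater)))
}

pearson_closed_form <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), df = n - 2))
}
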