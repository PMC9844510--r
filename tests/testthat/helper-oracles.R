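# Independent oracles used across the suite.

# the multisine written out term by term (independent of the package's
# vectorised evaluation path)
oracle_multisine <- function(tstar) {
  -7.8 * sin(0.48 * tstar) + 1.6 * sin(1.12 * tstar) +
    9.4 * sin(1.48 * tstar) - 10.6 * sin(2.56 * tstar)
}

# brute-force Benjamini-Hochberg step-up: sort, compare p_(i) to i*q/m,
# adjusted value = min over j >= i of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
oracle_signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# dense-grid zero scan of the target (0.01 ms steps), refined by uniroot
oracle_target_zeros <- function(step = 1e-5) {
  g <- seq(0, 25, by = step)
  v <- oracle_multisine(g)
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(oracle_multisine, c(g[i], g[i + 1L]), tol = 1e-12)$root
  }, numeric(1))
  sort(unique(c(g[abs(v) < 1e-9], roots)))
}
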