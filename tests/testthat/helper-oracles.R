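# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood code paths: densities are written out in raw
# log-gamma terms (or integrated numerically), tails are summed directly.

# beta-binomial log likelihood over a parameter grid (vectorized in the
# parameters), from first principles
oracle_grid_ll <- function(i, t, alpha, beta) {
  colSums(lgamma(outer(i, alpha, "+")) + lgamma(outer(t - i, beta, "+")) -
            lgamma(outer(t, alpha + beta, "+"))) +
    sum(lgamma(t + 1) - lgamma(i + 1) - lgamma(t - i + 1)) -
    length(i) * (lgamma(alpha) + lgamma(beta) - lgamma(alpha + beta))
}

# beta-binomial pmf by brute-force quadrature of the binomial against the
# beta density (midpoint rule, 1e6 points)
oracle_pmf_quadrature <- function(i, t, alpha, beta, n_points = 1e6) {
  p <- (seq_len(n_points) - 0.5) / n_points
  w <- stats::dbeta(p, alpha, beta) / n_points
  vapply(i, function(ii) sum(stats::dbinom(ii, t, p) * w), 0)
}

# upper-tail probability by direct summation of raw log-gamma densities
oracle_upper_tail <- function(i, t, alpha, beta) {
  if (i <= 0) return(1)
  ks <- i:t
  lp <- lgamma(t + 1) - lgamma(ks + 1) - lgamma(t - ks + 1) +
    lgamma(ks + alpha) + lgamma(t - ks + beta) -
    lgamma(t + alpha + beta) -
    (lgamma(alpha) + lgamma(beta) - lgamma(alpha + beta))
  sum(exp(lp))
}

# maximum grid likelihood at the resolutions used for oracle-equivalence
# checks
oracle_best_one_group <- function(i, t, omega_max = 200) {
  g <- expand.grid(psi = seq(0.005, 0.995, length.out = 200),
                   om = seq(2.01, omega_max + 1.99, length.out = 200))
  max(oracle_grid_ll(i, t, g$om * g$psi, g$om * (1 - g$psi)))
}

oracle_best_two_group <- function(i1, t1, i2, t2, omega_max = 200) {
  ps <- seq(0.005, 0.995, length.out = 100)
  best <- -Inf
  for (om in seq(2.01, omega_max + 1.99, length.out = 100)) {
    best <- max(best,
                max(oracle_grid_ll(i1, t1, om * ps, om * (1 - ps))) +
                  max(oracle_grid_ll(i2, t2, om * ps, om * (1 - ps))))
  }
  best
}

oracle_best_reference <- function(i, t, beta_max = 80) {
  g <- expand.grid(a = seq(1 / beta_max + 1e-4, 1, length.out = 300),
                   b = seq(1 + 1e-4, beta_max, length.out = 300))
  max(oracle_grid_ll(i, t, g$a, g$b))
}

# random valid splice events for property tests
random_splice_event <- function(k, rng_offset = 0L) {
  type <- sample(c("ES", "IR", "A3", "A5", "MX"), 1L)
  base <- sample(1000:1e6, 1L) + rng_offset
  d1 <- base; a1 <- d1 + sample(50:500, 1L)
  d2 <- a1 + sample(50:500, 1L); a2 <- d2 + sample(50:500, 1L)
  strand <- sample(c("+", "-"), 1L)
  contig <- as.character(sample(1:5, 1L))
  id <- sprintf("rnd%06d", k)
  switch(type,
    ES = splice_event(id, "G", contig, strand, "ES",
                      rbind(c(d1, a1), c(d2, a2)), c(d1, a2)),
    IR = splice_event(id, "G", contig, strand, "IR", c(d1, a1),
                      matrix(integer(0), ncol = 2)),
    A3 = splice_event(id, "G", contig, strand, "A3", c(d1, a1),
                      c(d1, a1 + sample(3:40, 1L))),
    A5 = splice_event(id, "G", contig, strand, "A5", c(d1, a1),
                      c(d1 - sample(3:40, 1L), a1)),
    MX = {
      b2 <- a2 + sample(50:500, 1L); b3 <- b2 + sample(50:500, 1L)
      splice_event(id, "G", contig, strand, "MX",
                   rbind(c(d1, a1), c(d2, b3)),
                   rbind(c(d1, a2), c(b2, b3)))
    })
}

# two-group simulation with named group map, shared by several tests
sim_two_groups <- function(n_events, n_per_group, psi1, psi2, omega, depth,
                           seed) {
  tab <- simulate_counts(
    n_events,
    list(list(label = "g1", n_samples = n_per_group, psi = psi1),
         list(label = "g2", n_samples = n_per_group, psi = psi2)),
    omega = omega, depth = depth, seed = seed)
  groups <- stats::setNames(
    ifelse(startsWith(tab$samples, "g1"), "g1", "g2"), tab$samples)
  list(table = tab, groups = groups)
}
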