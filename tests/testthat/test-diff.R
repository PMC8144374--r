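test_that("one-group fit seeks boundaries and symmetric optima", {
  # all reads support isoform 1
  f <- fit_one_group(rep(40L, 6), rep(40L, 6))
  expect_gt(f$psi, 0.99)
  # perfectly balanced deep counts
  f <- fit_one_group(rep(100L, 8), rep(200L, 8))
  expect_lt(abs(f$psi - 0.5), 0.01)
  # zero-depth samples dropped; all-zero flagged
  f <- fit_one_group(c(3L, 0L), c(9L, 0L))
  expect_identical(f$n_used, 1L)
  expect_identical(fit_one_group(c(0L, 0L), c(0L, 0L))$fit_status,
                   "insufficient")
})

test_that("optimizer matches exhaustive grid search on small instances", {
  set.seed(61)
  for (r in 1:60) {
    n <- sample(3:8, 1)
    t <- sample(0:30, n, replace = TRUE)
    t[1] <- max(t[1], 1L)
    i <- rbinom(n, t, runif(1, 0.05, 0.95))
    u <- t > 0
    f <- fit_one_group(i, t)
    expect_lt(abs(f$loglik - oracle_best_one_group(i[u], t[u])), 0.1)
  }
  for (r in 1:40) {
    n <- sample(3:6, 1)
    t1 <- sample(1:30, n, replace = TRUE)
    t2 <- sample(1:30, n, replace = TRUE)
    i1 <- rbinom(n, t1, runif(1, 0.05, 0.95))
    i2 <- rbinom(n, t2, runif(1, 0.05, 0.95))
    f <- fit_two_group(i1, t1, i2, t2)
    expect_lt(abs(f$loglik - oracle_best_two_group(i1, t1, i2, t2)), 0.1)
  }
})

test_that("two-group fit nests the one-group fit", {
  set.seed(62)
  i <- rbinom(8, 50, 0.4); t <- rep(50L, 8)
  one <- fit_one_group(c(i, i), c(t, t))
  two <- fit_two_group(i, t, i, t)
  expect_lt(abs(two$psi1 - two$psi2), 0.02)
  expect_gte(two$loglik, one$loglik - 1e-6)
  # clear separation recovered
  sep <- fit_two_group(rbinom(6, 200, 0.1), rep(200L, 6),
                       rbinom(6, 200, 0.9), rep(200L, 6))
  expect_lt(sep$psi1, 0.2)
  expect_gt(sep$psi2, 0.8)
})

test_that("identical groups give a null LR and symmetry is exact", {
  sim <- sim_two_groups(30, 6, 0.4, 0.4, omega = 40, depth = 50, seed = 63)
  # same samples duplicated into both labels
  dup <- stats::setNames(rep(c("x", "y"), each = length(sim$table$samples)),
                         rep(sim$table$samples, 2))
  # build duplicated table: same counts under two label sets
  tab2 <- sim$table
  tab2$iso1 <- cbind(sim$table$iso1, sim$table$iso1)
  tab2$iso2 <- cbind(sim$table$iso2, sim$table$iso2)
  colnames(tab2$iso1) <- colnames(tab2$iso2) <-
    c(paste0(sim$table$samples, ".a"), paste0(sim$table$samples, ".b"))
  tab2$samples <- colnames(tab2$iso1)
  grp <- stats::setNames(rep(c("x", "y"),
                             each = length(sim$table$samples)),
                         tab2$samples)
  res <- diff_test(tab2, grp)
  expect_true(all(res$lr <= 1e-4))
  # label symmetries on the original table
  r1 <- diff_test(sim$table, sim$groups)
  swapped <- sim$table
  swapped$iso1 <- sim$table$iso2
  swapped$iso2 <- sim$table$iso1
  r2 <- diff_test(swapped, sim$groups)
  o1 <- order(r1$event_id); o2 <- order(r2$event_id)
  expect_lt(max(abs(r1$lr[o1] - r2$lr[o2]), na.rm = TRUE), 1e-6)
  expect_equal(r1$psi_group1[o1], 1 - r2$psi_group1[o2], tolerance = 1e-9)
  g_sw <- stats::setNames(ifelse(sim$groups == "g1", "g2", "g1"),
                          names(sim$groups))
  r3 <- diff_test(sim$table, g_sw)
  o3 <- order(r3$event_id)
  expect_lt(max(abs(r1$lr[o1] - r3$lr[o3]), na.rm = TRUE), 1e-6)
})

test_that("LR is never negative and output is ranked", {
  sim <- sim_two_groups(60, 5, 0.3, 0.55, omega = 25, depth = 30, seed = 64)
  res <- diff_test(sim$table, sim$groups)
  expect_true(all(res$lr >= -1e-6, na.rm = TRUE))
  lr <- res$lr[!is.na(res$lr)]
  expect_true(all(diff(lr) <= 0))
  expect_identical(
    res$group_increased_alt[!is.na(res$lr)],
    ifelse(res$psi_group1[!is.na(res$lr)] <= res$psi_group2[!is.na(res$lr)],
           "g1", "g2"))
})

test_that("differential power and PSI recovery at the design separation", {
  sim <- sim_two_groups(120, 10, 0.3, 0.7, omega = 50, depth = 100,
                        seed = 65)
  res <- diff_test(sim$table, sim$groups)
  expect_gte(mean(res$lr > 8, na.rm = TRUE), 0.95)
  err <- c(abs(res$psi_group1 - 0.3), abs(res$psi_group2 - 0.7))
  expect_lt(median(err, na.rm = TRUE), 0.05)
})

test_that("unknown samples and degenerate groupings are rejected", {
  sim <- sim_two_groups(2, 3, 0.5, 0.5, omega = 30, depth = 30, seed = 66)
  bad <- c(sim$groups, ghost = "g1")
  expect_error(diff_test(sim$table, bad), "unknown sample")
  one_label <- stats::setNames(rep("g1", length(sim$table$samples)),
                               sim$table$samples)
  expect_error(diff_test(sim$table, one_label), "two group labels")
})
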