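test_that("minor-isoform orientation follows mean reference PSI", {
  expect_identical(orient_minor(c(1L, 2L, 0L), c(9L, 8L, 10L)), 1L)
  expect_identical(orient_minor(c(9L, 8L), c(1L, 2L)), 2L)
  # exact tie at 0.5 goes to isoform 1
  expect_identical(orient_minor(c(5L, 5L), c(5L, 5L)), 1L)
  expect_identical(orient_minor(c(0L, 0L), c(0L, 0L)), NA_integer_)
  # zero-depth samples do not influence the mean
  expect_identical(orient_minor(c(0L, 9L), c(0L, 1L)), 2L)
})

test_that("zero-minor reference uses the closed form exactly", {
  f <- fit_reference(rep(0L, 5), c(10L, 10L, 10L, 10L, 10L), beta_max = 80)
  expect_identical(f$fit_status, "zero_minor")
  expect_identical(f$alpha_R, 1)
  expect_identical(f$beta_R, 50)
  f2 <- fit_reference(rep(0L, 5), rep(100L, 5), beta_max = 80)
  expect_identical(f2$beta_R, 80)
})

test_that("reference fit matches the constrained grid oracle", {
  set.seed(71)
  tested <- 0
  while (tested < 60) {
    n <- sample(4:10, 1)
    t <- sample(1:40, n, replace = TRUE)
    i <- rbinom(n, t, runif(1, 0.02, 0.4))
    f <- fit_reference(i, t, beta_max = 80)
    if (f$fit_status == "zero_minor") next
    expect_lt(abs(f$loglik - oracle_best_reference(i, t)), 0.1)
    tested <- tested + 1
  }
})

test_that("scores equal the direct tail summation and the uniform identity", {
  fit_unif <- list(alpha_R = 1, beta_R = 1)
  expect_equal(outlier_score(9L, 9L, fit_unif), 1)
  expect_identical(outlier_score(0L, 50L, list(alpha_R = 0.5, beta_R = 40)),
                   0)
  expect_true(is.na(outlier_score(0L, 0L, fit_unif)))
  # uniform closed form to 1e-12 across depths
  for (t in c(1L, 7L, 50L, 200L)) {
    i <- seq_len(t)
    got <- vapply(i, outlier_score, 0, T_s = t, fit = fit_unif)
    expect_equal(got, -log10((t - i + 1) / (t + 1)), tolerance = 1e-12)
  }
  # a fitted-parameter case against the summation oracle
  fit <- list(alpha_R = 1, beta_R = 50)
  expect_equal(outlier_score(60L, 100L, fit),
               -log10(oracle_upper_tail(60, 100, 1, 50)),
               tolerance = 1e-10)
})

test_that("score is non-decreasing in the minor count", {
  fit <- list(alpha_R = 0.8, beta_R = 35)
  for (t in c(1L, 13L, 97L, 200L)) {
    sc <- vapply(0:t, outlier_score, 0, T_s = t, fit = fit)
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("reference-like samples score low; real outliers score high", {
  tab <- simulate_counts(
    60, list(list(label = "ref", n_samples = 25, psi = 0.05),
             list(label = "held", n_samples = 10, psi = 0.05)),
    omega = 60, depth = 80, seed = 72)
  refs <- grep("^ref", tab$samples, value = TRUE)
  held <- grep("^held", tab$samples, value = TRUE)
  sc <- outlier_scan(tab, refs, held)
  expect_lte(median(sc$score, na.rm = TRUE), 1)
  expect_lte(mean(sc$score > 10, na.rm = TRUE), 0.005)
  # a sample drawn from the panel itself is unremarkable
  self <- outlier_scan(tab, refs, refs[1])
  expect_lte(median(self$score, na.rm = TRUE), 1)
  # near-invariant reference with a heavy minor-isoform excess in the test:
  # the operating threshold of 10 is reachable
  ev <- tab$events[1]
  ref_iso2 <- matrix(c(rep(100L, 20), 100L), 1,
                     dimnames = list(NULL, c(paste0("r", 1:20), "case")))
  ref_iso1 <- matrix(c(rep(0L, 20), 40L), 1,
                     dimnames = list(NULL, colnames(ref_iso2)))
  ref_iso2[1, 21] <- 60L
  tab2 <- event_count_table(ev, ref_iso1, ref_iso2)
  sc2 <- outlier_scan(tab2, paste0("r", 1:20), "case")
  expect_gt(sc2$score, 10)
  expect_true(sc2$passes_threshold)
})

test_that("min-combination keeps the smaller score and propagates missing", {
  ev <- lapply(1:2, random_splice_event)
  mk <- function(scores) {
    data.frame(event_id = c("rnd000001", "rnd000002"),
               sample = "s", score = scores,
               passes_threshold = FALSE, alpha_R = 1, beta_R = 2,
               fit_status = "optimized", stringsAsFactors = FALSE)
  }
  a <- mk(c(4.8, NA)); b <- mk(c(7.2, 5.0))
  got <- combine_scores_min(a, b)
  expect_equal(got$score, c(4.8, NA))
  expect_equal(combine_scores_min(b, b)$score, b$score)
  bad <- mk(c(1, 2)); bad$event_id <- c("other1", "other2")
  expect_error(combine_scores_min(a, bad), "different event/sample")
})
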