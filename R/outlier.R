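#' @name outlier_test
#' @title Beta-binomial splicing outlier score
#'
#' @description
#' For each event, a beta distribution is fitted to the minor-isoform usage
#' of a reference panel, with shapes constrained to
#' `1/beta_max < alpha_R <= 1` and `1 < beta_R <= beta_max` so that the
#' density is strictly decreasing: under the reference, high minor-isoform
#' PSI is always unlikely. A test sample with minor count `I_s` out of
#' `T_s` reads is scored by the upper-tail probability of its count under
#' the fitted beta-binomial:
#' `score = -log10 P(X >= I_s)`, `X ~ BetaBinomial(T_s, alpha_R, beta_R)`.
#' Scores are non-negative, zero when `I_s = 0`, and conventionally
#' thresholded at 10.
#'
#' The score is one-sided by construction: only an excess of the minor
#' isoform can be detected, since a deficit is never in the tail of a
#' strictly decreasing density.
NULL

#' Orient the minor isoform on the reference panel
#'
#' The minor isoform is the one with mean PSI below 0.5 across covered
#' reference samples (zero-depth samples excluded). An exact tie at 0.5 is
#' broken toward isoform 1. Orientation is computed on the reference only
#' and applied unchanged to test samples.
#'
#' @param I1,I2 reference isoform count vectors.
#' @return 1L or 2L, or NA if no reference sample has coverage.
#' @export
orient_minor <- function(I1, I2) {
  tot <- I1 + I2
  use <- tot > 0
  if (!any(use)) return(NA_integer_)
  mean_psi1 <- mean(I1[use] / tot[use])
  if (mean_psi1 <= 0.5) 1L else 2L
}

#' Fit the reference beta distribution
#'
#' Maximum-likelihood `(alpha_R, beta_R)` for the minor-isoform counts of
#' the reference panel, within the strictly-decreasing constraints (logistic
#' reparameterization `alpha_R = (1 - 1/beta_max)/(1+exp(a)) + 1/beta_max`,
#' `beta_R = (beta_max - 1)/(1+exp(b)) + 1`). If the panel contains no
#' minor-isoform reads at all, the closed form `alpha_R = 1`,
#' `beta_R = min(beta_max, sum(T_n))` is used (`fit_status = "zero_minor"`).
#'
#' @param I_minor minor-isoform counts (oriented by [orient_minor()]).
#' @param T total counts, same length.
#' @param beta_max constraint on `beta_R` (default 80).
#' @return list with `alpha_R`, `beta_R`, `loglik`, `n_reference`,
#'   `fit_status` in `{"optimized", "zero_minor", "insufficient"}`.
#' @export
fit_reference <- function(I_minor, T, beta_max = 80) {
  stopifnot(length(I_minor) == length(T), beta_max > 1)
  use <- which(T > 0)
  if (!length(use))
    return(list(alpha_R = NA_real_, beta_R = NA_real_, loglik = NA_real_,
                n_reference = 0L, fit_status = "insufficient"))
  i <- as.numeric(I_minor[use]); t <- as.numeric(T[use])
  if (sum(i) == 0) {
    ab <- c(1, min(beta_max, sum(t)))
    nll <- bb_negll(i, t)
    return(list(alpha_R = ab[1L], beta_R = ab[2L],
                loglik = -nll(ab[1L], ab[2L]), n_reference = length(use),
                fit_status = "zero_minor"))
  }
  alpha_of <- function(a) (1 - 1 / beta_max) / (1 + exp(a)) + 1 / beta_max
  beta_of <- function(b) (beta_max - 1) / (1 + exp(b)) + 1
  nll <- bb_negll(i, t)
  obj <- function(p) nll(alpha_of(p[1]), beta_of(p[2]))
  a0 <- min(0.9, mean(i / t) + 0.05)
  a0 <- max(a0, 1 / beta_max + 1e-6)
  par0 <- c(log((1 - 1 / beta_max) / (a0 - 1 / beta_max) - 1),
            log((beta_max - 1) / (beta_max / 2 - 1) - 1))
  res <- optimize_nm_bfgs(par0, obj)
  if (is.null(res) || !is.finite(res$value))
    return(list(alpha_R = alpha_of(par0[1]), beta_R = beta_of(par0[2]),
                loglik = -obj(par0), n_reference = length(use),
                fit_status = "failed"))
  if (res$value > obj(par0)) res <- list(par = par0, value = obj(par0))
  list(alpha_R = alpha_of(res$par[1]), beta_R = beta_of(res$par[2]),
       loglik = -res$value, n_reference = length(use),
       fit_status = "optimized")
}

#' Outlier score of one observation
#'
#' `-log10 P(X >= I_s)` for `X ~ BetaBinomial(T_s, alpha_R, beta_R)`; the
#' tail is accumulated in log space, so the score is finite for any valid
#' input. `I_s = 0` scores exactly 0; `T_s = 0` yields NA (no evidence).
#'
#' @param I_s minor-isoform count of the test sample.
#' @param T_s total count of the test sample.
#' @param fit a [fit_reference()] result (or any list with `alpha_R`,
#'   `beta_R`).
#' @return non-negative score, or NA.
#' @export
outlier_score <- function(I_s, T_s, fit) {
  if (is.na(T_s) || T_s == 0) return(NA_real_)
  if (I_s < 0 || I_s > T_s)
    stop("outlier_score: require 0 <= I_s <= T_s", call. = FALSE)
  if (I_s == 0) return(0)
  -betabin_upper_logtail(I_s, T_s, fit$alpha_R, fit$beta_R) / log(10)
}

#' Outlier scan over a count table
#'
#' Per event: orients the minor isoform on the reference panel, fits the
#' reference beta, and scores every test sample. Events whose reference fit
#' is impossible (no covered reference sample) are reported with
#' `fit_status = "insufficient"` and NA scores.
#'
#' @param table an [event_count_table()].
#' @param reference_samples,test_samples character vectors of sample ids
#'   (may overlap).
#' @param beta_max reference-fit constraint (default 80).
#' @param threshold score cutoff used for the `passes_threshold` flag
#'   (default 10).
#' @return data.frame with one row per event x test sample: `event_id`,
#'   `event_jid`, `sample`, `minor_isoform`, `minor_count`, `total`,
#'   `alpha_R`, `beta_R`, `score`, `passes_threshold`, `fit_status`.
#' @export
outlier_scan <- function(table, reference_samples, test_samples,
                         beta_max = 80, threshold = 10) {
  unknown <- setdiff(c(reference_samples, test_samples), table$samples)
  if (length(unknown))
    stop(sprintf("outlier_scan: unknown sample(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  tot <- total_counts(table)
  rows <- vector("list", length(table$events))
  for (k in seq_along(table$events)) {
    ev <- table$events[[k]]
    i1r <- table$iso1[k, reference_samples]
    i2r <- table$iso2[k, reference_samples]
    minor <- orient_minor(i1r, i2r)
    if (is.na(minor)) {
      fit <- list(alpha_R = NA_real_, beta_R = NA_real_,
                  fit_status = "insufficient")
    } else {
      Im <- if (minor == 1L) i1r else i2r
      fit <- fit_reference(Im, i1r + i2r, beta_max)
    }
    It <- if (identical(minor, 2L)) table$iso2[k, test_samples] else
      table$iso1[k, test_samples]
    Tt <- tot[k, test_samples]
    sc <- rep(NA_real_, length(test_samples))
    if (!is.na(minor) && fit$fit_status %in% c("optimized", "zero_minor"))
      sc <- vapply(seq_along(test_samples),
                   function(j) outlier_score(It[j], Tt[j], fit), 0)
    rows[[k]] <- data.frame(
      event_id = ev$event_id, event_jid = make_event_jid(ev),
      sample = test_samples, minor_isoform = minor,
      minor_count = as.integer(It), total = as.integer(Tt),
      alpha_R = fit$alpha_R, beta_R = fit$beta_R, score = sc,
      passes_threshold = !is.na(sc) & sc > threshold,
      fit_status = fit$fit_status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine two outlier runs by elementwise minimum
#'
#' Conservative combination of outlier scores computed against two
#' different reference panels: each event/sample keeps the smaller of the
#' two scores, and a score missing in either run stays missing (an event
#' only counts as an outlier if both panels support it).
#'
#' @param scores_a,scores_b [outlier_scan()] results over the same events
#'   and test samples.
#' @return data.frame shaped like `scores_a` with combined `score` and
#'   recomputed `passes_threshold` (threshold taken from `threshold`).
#' @param threshold cutoff for the recomputed pass flag (default 10).
#' @export
combine_scores_min <- function(scores_a, scores_b, threshold = 10) {
  key_a <- paste(scores_a$event_id, scores_a$sample)
  key_b <- paste(scores_b$event_id, scores_b$sample)
  if (!identical(sort(key_a), sort(key_b)))
    stop("combine_scores_min: runs index different event/sample pairs",
         call. = FALSE)
  scores_b <- scores_b[match(key_a, key_b), , drop = FALSE]
  out <- scores_a
  out$score <- ifelse(is.na(scores_a$score) | is.na(scores_b$score),
                      NA_real_, pmin(scores_a$score, scores_b$score))
  out$passes_threshold <- !is.na(out$score) & out$score > threshold
  out$alpha_R <- NULL; out$beta_R <- NULL; out$fit_status <- NULL
  out
}
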