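#' Welch t-test on PSI values
#'
#' Two-sided two-sample t-test with unequal variances (Welch-Satterthwaite
#' degrees of freedom) comparing PSI values between two groups. Missing PSI
#' values (zero or masked depth) are dropped first. With fewer than two
#' values in a group the result is missing. If both groups have zero
#' variance the statistic is degenerate: the p-value is reported as 1 when
#' the means are equal and 0 otherwise, with `degenerate = TRUE`, so that
#' benchmark sweeps complete instead of erroring.
#'
#' @param psi_group1,psi_group2 numeric PSI vectors (NAs allowed).
#' @return list with `p_value`, `t`, `df`, `n_used1`, `n_used2`,
#'   `degenerate`.
#' @export
welch_t_psi <- function(psi_group1, psi_group2) {
  x <- psi_group1[!is.na(psi_group1)]
  y <- psi_group2[!is.na(psi_group2)]
  out <- list(p_value = NA_real_, t = NA_real_, df = NA_real_,
              n_used1 = length(x), n_used2 = length(y), degenerate = FALSE)
  if (length(x) < 2L || length(y) < 2L) return(out)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    out$degenerate <- TRUE
    out$p_value <- if (mean(x) == mean(y)) 1 else 0
    out$t <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    return(out)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  out$p_value <- tt$p.value
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out
}

#' MAD outlier score
#'
#' Signed deviation of the test-sample PSI from the reference median,
#' normalized by the median absolute deviation floored at 0.01:
#' `(x_s - median(x_R)) / max(median(|x_R - median(x_R)|), 0.01)`.
#'
#' @param x_s test-sample PSI.
#' @param x_R reference PSI vector (NAs dropped).
#' @return signed score; NA if the reference is empty after dropping NAs or
#'   `x_s` is missing.
#' @export
mad_score <- function(x_s, x_R) {
  x_R <- x_R[!is.na(x_R)]
  if (!length(x_R) || is.na(x_s)) return(NA_real_)
  med <- stats::median(x_R)
  (x_s - med) / max(stats::median(abs(x_R - med)), 0.01)
}

#' IQR outlier score
#'
#' Zero inside the reference interquartile box; outside, the distance to the
#' nearer quartile normalized by the interquartile range floored at 0.01.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Always non-negative.
#'
#' @inheritParams mad_score
#' @export
iqr_score <- function(x_s, x_R) {
  x_R <- x_R[!is.na(x_R)]
  if (!length(x_R) || is.na(x_s)) return(NA_real_)
  q <- stats::quantile(x_R, c(0.25, 0.75), names = FALSE, type = 7)
  denom <- max(q[2L] - q[1L], 0.01)
  if (x_s < q[1L]) (q[1L] - x_s) / denom
  else if (x_s > q[2L]) (x_s - q[2L]) / denom
  else 0
}

#' Baseline differential test over a count table
#'
#' Welch t-test on PSI per event. Respects the table's depth mask (see
#' [mask_low_depth()]).
#'
#' @param table an [event_count_table()].
#' @param groups named vector mapping samples to two group labels, as in
#'   [diff_test()].
#' @return data.frame with `event_id`, `event_jid`, `method`, `value` (the
#'   p-value), `t`, `df`, `n_used_group1`, `n_used_group2`, `degenerate`,
#'   `masked`.
#' @export
baseline_diff <- function(table, groups) {
  groups <- stats::setNames(as.character(groups), names(groups))
  unknown <- setdiff(names(groups), table$samples)
  if (length(unknown))
    stop(sprintf("baseline_diff: unknown sample(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  labs <- sort(unique(groups))
  if (length(labs) != 2L)
    stop("baseline_diff: need exactly two group labels", call. = FALSE)
  psi <- psi_matrix(table)
  s1 <- names(groups)[groups == labs[1L]]
  s2 <- names(groups)[groups == labs[2L]]
  rows <- lapply(seq_along(table$events), function(k) {
    w <- welch_t_psi(psi[k, s1], psi[k, s2])
    data.frame(event_id = names(table$events)[k],
               event_jid = make_event_jid(table$events[[k]]),
               method = "ttest", value = w$p_value, t = w$t, df = w$df,
               n_used_group1 = w$n_used1, n_used_group2 = w$n_used2,
               degenerate = w$degenerate, masked = table$min_depth > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline outlier scores over a count table
#'
#' MAD or IQR scores of each test sample against the reference panel's PSI
#' distribution, per event. Respects the table's depth mask.
#'
#' @inheritParams outlier_scan
#' @param method "mad" or "iqr".
#' @return data.frame with `event_id`, `event_jid`, `sample`, `method`,
#'   `value`, `n_used`, `masked`.
#' @export
baseline_outlier <- function(table, reference_samples, test_samples,
                             method = c("mad", "iqr")) {
  method <- match.arg(method)
  unknown <- setdiff(c(reference_samples, test_samples), table$samples)
  if (length(unknown))
    stop(sprintf("baseline_outlier: unknown sample(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  psi <- psi_matrix(table)
  score_fun <- if (method == "mad") mad_score else iqr_score
  rows <- lapply(seq_along(table$events), function(k) {
    xr <- psi[k, reference_samples]
    data.frame(event_id = names(table$events)[k],
               event_jid = make_event_jid(table$events[[k]]),
               sample = test_samples, method = method,
               value = vapply(psi[k, test_samples], score_fun, 0, x_R = xr),
               n_used = sum(!is.na(xr)), masked = table$min_depth > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
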