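#' @name diff_test
#' @title Beta-binomial differential splicing test
#'
#' @description
#' Isoform counts for one splice event are modeled as beta-binomial: reads
#' supporting isoform 1 are successes among the total reads covering the
#' event, with the per-sample PSI drawn from a beta distribution capturing
#' biological variation. The beta is reparameterized by its mean
#' `psi = alpha/(alpha+beta)` and concentration `omega = alpha+beta`. The
#' one-group model fits a single `(psi, omega)` to all samples; the
#' two-group model gives each group its own `psi` but a shared `omega`. The
#' test statistic is the log-likelihood improvement
#' `lr = loglik(two-group) - loglik(one-group)`, non-negative at the optimum
#' because the models are nested; events are conventionally flagged at
#' `lr > 8`.
#'
#' Fits use Nelder-Mead (BFGS fallback) on logistic-transformed
#' coordinates `omega = omega_max/(1+exp(a)) + 2`, `psi = 1/(1+exp(b))`,
#' which constrain `2 < omega < omega_max + 2` and `0 < psi < 1`. Samples
#' with zero depth contribute zero log density and are dropped from the
#' used-sample counts; an event needs at least 2 covered samples per group
#' to be scored.
NULL

PSI_EPS <- 1e-9

omega_of <- function(a, omega_max) omega_max / (1 + exp(a)) + 2
psi_of <- function(b) pmin(pmax(1 / (1 + exp(b)), PSI_EPS), 1 - PSI_EPS)
b_of_psi <- function(psi) log((1 - psi) / psi)

# negative log likelihood factory for a set of samples; precomputes the
# lchoose term, which does not depend on the parameters
bb_negll <- function(i, t) {
  lch <- lchoose(t, i)
  function(alpha, beta) {
    -sum(lch + lbeta(i + alpha, t - i + beta) - lbeta(alpha, beta))
  }
}

# Canonical isoform orientation for fitting: work on whichever labeling has
# the smaller pooled count (ties broken elementwise), so that swapping the
# isoform columns reproduces bit-identical optimizer trajectories and the LR
# is exactly invariant under the swap. Decided with integer arithmetic only.
should_flip_iso <- function(i, t) {
  si <- sum(i); st <- sum(t)
  if (2 * si != st) return(2 * si > st)
  d <- i - (t - i)
  nz <- which(d != 0)
  if (length(nz)) d[nz[1L]] > 0 else FALSE
}

optimize_nm_bfgs <- function(par, fn, maxit = 500L, reltol = 1e-8) {
  res <- tryCatch(
    stats::optim(par, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL)
  if (is.null(res) || res$convergence != 0 || !is.finite(res$value)) {
    res2 <- tryCatch(
      stats::optim(if (is.null(res)) par else res$par, fn, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(res2) && is.finite(res2$value) &&
        (is.null(res) || res2$value <= res$value))
      res <- res2
  }
  res
}

#' Fit the one-group beta-binomial model
#'
#' Maximum-likelihood `(psi, omega)` for a single set of samples. Zero-depth
#' samples are ignored. Initialization: `psi` at the pooled moment estimate,
#' `omega` at `omega_max/2 + 2`.
#'
#' @param I,T integer vectors of isoform-1 and total counts, same length.
#' @param omega_max upper constraint on the concentration (default 200).
#' @return list with `psi`, `omega`, `loglik`, `n_used`, `fit_status`
#'   ("optimized" or "insufficient").
#' @export
fit_one_group <- function(I, T, omega_max = 200) {
  stopifnot(length(I) == length(T))
  use <- which(T > 0)
  if (!length(use))
    return(list(psi = NA_real_, omega = NA_real_, loglik = NA_real_,
                n_used = 0L, fit_status = "insufficient"))
  i <- as.numeric(I[use]); t <- as.numeric(T[use])
  flip <- should_flip_iso(i, t)
  if (flip) i <- t - i
  nll <- bb_negll(i, t)
  obj <- function(p) nll(omega_of(p[1], omega_max) * psi_of(p[2]),
                         omega_of(p[1], omega_max) * (1 - psi_of(p[2])))
  psi0 <- (sum(i) + 0.5) / (sum(t) + 1)
  par0 <- c(0, b_of_psi(psi0))
  res <- optimize_nm_bfgs(par0, obj)
  if (is.null(res) || !is.finite(res$value))
    return(list(psi = if (flip) 1 - psi0 else psi0,
                omega = omega_of(0, omega_max),
                loglik = -obj(par0), n_used = length(use),
                fit_status = "failed"))
  if (res$value > obj(par0)) res <- list(par = par0, value = obj(par0))
  psi_hat <- psi_of(res$par[2])
  list(psi = if (flip) 1 - psi_hat else psi_hat,
       omega = omega_of(res$par[1], omega_max),
       loglik = -res$value, n_used = length(use), fit_status = "optimized")
}

#' Fit the two-group beta-binomial model
#'
#' Group-specific `psi` with a shared `omega`, maximizing the summed log
#' density over both groups.
#'
#' @param I1,T1,I2,T2 per-group count vectors.
#' @inheritParams fit_one_group
#' @return list with `psi1`, `psi2`, `omega`, `loglik`, `n_used1`,
#'   `n_used2`, `fit_status`.
#' @export
fit_two_group <- function(I1, T1, I2, T2, omega_max = 200) {
  u1 <- which(T1 > 0); u2 <- which(T2 > 0)
  if (!length(u1) || !length(u2))
    return(list(psi1 = NA_real_, psi2 = NA_real_, omega = NA_real_,
                loglik = NA_real_, n_used1 = length(u1),
                n_used2 = length(u2), fit_status = "insufficient"))
  i1 <- as.numeric(I1[u1]); t1 <- as.numeric(T1[u1])
  i2 <- as.numeric(I2[u2]); t2 <- as.numeric(T2[u2])
  # orientation decided on the pooled data so it agrees with the one-group
  # fit used for the LR
  flip <- should_flip_iso(c(i1, i2), c(t1, t2))
  if (flip) { i1 <- t1 - i1; i2 <- t2 - i2 }
  nll1 <- bb_negll(i1, t1)
  nll2 <- bb_negll(i2, t2)
  obj <- function(p) {
    om <- omega_of(p[1], omega_max)
    ps1 <- psi_of(p[2]); ps2 <- psi_of(p[3])
    nll1(om * ps1, om * (1 - ps1)) + nll2(om * ps2, om * (1 - ps2))
  }
  p10 <- (sum(i1) + 0.5) / (sum(t1) + 1)
  p20 <- (sum(i2) + 0.5) / (sum(t2) + 1)
  par0 <- c(0, b_of_psi(p10), b_of_psi(p20))
  res <- optimize_nm_bfgs(par0, obj)
  unflip <- function(p) if (flip) 1 - p else p
  if (is.null(res) || !is.finite(res$value))
    return(list(psi1 = unflip(p10), psi2 = unflip(p20),
                omega = omega_of(0, omega_max),
                loglik = -obj(par0), n_used1 = length(u1),
                n_used2 = length(u2), fit_status = "failed"))
  if (res$value > obj(par0)) res <- list(par = par0, value = obj(par0))
  list(psi1 = unflip(psi_of(res$par[2])), psi2 = unflip(psi_of(res$par[3])),
       omega = omega_of(res$par[1], omega_max), loglik = -res$value,
       n_used1 = length(u1), n_used2 = length(u2), fit_status = "optimized")
}

#' Two-group differential splicing test
#'
#' Runs the beta-binomial likelihood-ratio test on every event of a count
#' table. `groups` maps each tested sample to one of two group labels.
#' Events with fewer than 2 covered samples in either group are flagged
#' `insufficient` and not scored. Results are sorted by `lr` descending
#' (ties broken on event_id).
#'
#' The `group_increased_alt` column reports the group with the higher
#' fitted PSI of isoform 2 (the "alt" isoform by table convention); protein
#' annotation recomputes this label for the specific alternative isoform of
#' the selected sequence pair.
#'
#' @param table an [event_count_table()].
#' @param groups named character vector (or factor) mapping sample id to
#'   group label; exactly two distinct labels.
#' @param omega_max concentration constraint (default 200).
#' @param lr_threshold flagging threshold on the statistic (default 8;
#'   affects only the `pass` column).
#' @return data.frame, one row per event: `event_id`, `event_jid`, `gene`,
#'   `event_type`, `lr`, `psi_group1`, `psi_group2`, `omega`,
#'   `group_increased_alt`, `n_used_group1`, `n_used_group2`, `fit_status`,
#'   `pass`, with group label order attached as attribute `group_labels`.
#' @export
diff_test <- function(table, groups, omega_max = 200, lr_threshold = 8) {
  groups <- stats::setNames(as.character(groups), names(groups))
  unknown <- setdiff(names(groups), table$samples)
  if (length(unknown))
    stop(sprintf("diff_test: unknown sample(s) in groups: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  labs <- sort(unique(groups))
  if (length(labs) != 2L)
    stop("diff_test: need exactly two group labels", call. = FALSE)
  s1 <- names(groups)[groups == labs[1L]]
  s2 <- names(groups)[groups == labs[2L]]
  tot <- total_counts(table)
  n <- length(table$events)
  out <- data.frame(
    event_id = names(table$events),
    event_jid = vapply(table$events, make_event_jid, ""),
    gene = vapply(table$events, `[[`, "", "gene_id"),
    event_type = vapply(table$events, `[[`, "", "event_type"),
    lr = NA_real_, psi_group1 = NA_real_, psi_group2 = NA_real_,
    omega = NA_real_, group_increased_alt = NA_character_,
    n_used_group1 = 0L, n_used_group2 = 0L,
    fit_status = "insufficient", pass = FALSE,
    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_len(n)) {
    I1 <- table$iso1[k, s1]; T1 <- tot[k, s1]
    I2 <- table$iso1[k, s2]; T2 <- tot[k, s2]
    out$n_used_group1[k] <- sum(T1 > 0)
    out$n_used_group2[k] <- sum(T2 > 0)
    if (out$n_used_group1[k] < 2L || out$n_used_group2[k] < 2L) next
    one <- fit_one_group(c(I1, I2), c(T1, T2), omega_max)
    two <- fit_two_group(I1, T1, I2, T2, omega_max)
    if (one$fit_status != "optimized" || two$fit_status != "optimized") {
      out$fit_status[k] <- "failed"
      next
    }
    # nested models: the two-group optimum cannot be worse than the shared
    # fit evaluated as a two-group model
    if (two$loglik < one$loglik) {
      two$loglik <- one$loglik
      two$psi1 <- two$psi2 <- one$psi
      two$omega <- one$omega
    }
    out$lr[k] <- two$loglik - one$loglik
    out$psi_group1[k] <- two$psi1
    out$psi_group2[k] <- two$psi2
    out$omega[k] <- two$omega
    # alt isoform of the diff table = isoform 2: more iso2 <=> smaller psi
    out$group_increased_alt[k] <- if (two$psi1 <= two$psi2) labs[1L] else labs[2L]
    out$fit_status[k] <- "optimized"
    out$pass[k] <- out$lr[k] > lr_threshold
  }
  out <- out[order(-ifelse(is.na(out$lr), -Inf, out$lr), out$event_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_labels") <- labs
  out
}
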