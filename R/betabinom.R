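#' Beta-binomial log density
#'
#' Log probability mass of observing `i` successes in `t` trials when the
#' success probability is Beta(alpha, beta) distributed. Computed entirely in
#' log space via [lchoose()] and [lbeta()], so it is finite for all valid
#' inputs, including large depths.
#'
#' With `t = 0` the density is 1 (log density 0): a sample with no coverage
#' carries no information and contributes nothing to a log likelihood.
#'
#' @param i integer vector, successes (reads supporting the tested isoform).
#' @param t integer vector, trials (total reads covering the event).
#' @param alpha,beta positive beta shape parameters.
#' @return numeric vector of log densities, recycled to the common length.
#' @examples
#' exp(betabin_logpdf(0:2, 2, 2, 2))  # 0.3 0.4 0.3
#' @export
betabin_logpdf <- function(i, t, alpha, beta) {
  n <- max(length(i), length(t), length(alpha), length(beta))
  i <- rep_len(as.numeric(i), n)
  t <- rep_len(as.numeric(t), n)
  alpha <- rep_len(as.numeric(alpha), n)
  beta <- rep_len(as.numeric(beta), n)
  if (any(i < 0 | t < 0 | i > t))
    stop("betabin_logpdf: require 0 <= i <= t", call. = FALSE)
  if (any(alpha <= 0 | beta <= 0))
    stop("betabin_logpdf: shape parameters must be positive", call. = FALSE)
  lchoose(t, i) + lbeta(i + alpha, t - i + beta) - lbeta(alpha, beta)
}

#' Beta-binomial upper-tail log probability
#'
#' log P(X >= i) for X ~ BetaBinomial(t, alpha, beta), summed in log space
#' (log-sum-exp over the exact log densities i..t), so scores remain finite
#' far into the tail.
#'
#' @inheritParams betabin_logpdf
#' @return log of the upper-tail probability (a single value; `i`, `t` must
#'   be scalars here).
#' @keywords internal
betabin_upper_logtail <- function(i, t, alpha, beta) {
  stopifnot(length(i) == 1L, length(t) == 1L)
  if (i <= 0) return(0)              # P(X >= 0) = 1
  lp <- betabin_logpdf(i:t, t, alpha, beta)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# log-sum-exp helper used by optimizer objectives
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
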