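#' Beta-binomial density parameterized by mean and intra-class correlation
#'
#' The beta-binomial is parameterized by its mean editing probability `prob`
#' and the intra-class correlation `rho` in `[0,1)`; `rho = 0` degenerates to
#' the ordinary binomial.  In terms of the usual shape parameters,
#' `a = prob * (1 - rho) / rho` and `b = (1 - prob) * (1 - rho) / rho`.
#'
#' @param x number of alternate reads.
#' @param size total reads.
#' @param prob mean success probability in `[0,1]`.
#' @param rho intra-class correlation in `[0,1)`.
#' @param log return the log density?
#' @return density (or log density), vectorized over `x`/`size`.
#' @export
dbetabinom <- function(x, size, prob, rho = 0, log = FALSE) {
  stopifnot(all(rho >= 0), all(rho < 1))
  if (all(rho == 0)) return(stats::dbinom(x, size, prob, log = log))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  # degenerate means: prob 0 or 1 make a or b zero; fall back to point mass
  deg <- prob <= 0 | prob >= 1
  if (any(deg)) {
    ll[deg] <- ifelse(x[deg] == round(prob * size)[deg], 0, -Inf)
  }
  if (log) ll else exp(ll)
}

#' Sample beta-binomial counts
#'
#' @param n number of draws.
#' @param size total reads (recycled).
#' @param prob mean success probability.
#' @param rho intra-class correlation; 0 gives binomial sampling.
#' @return integer vector of alternate-read counts.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  if (rho == 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}
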