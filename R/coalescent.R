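## Heterochronous coalescent: likelihood of a dated tree under a constant or
## time-varying population size, the closed-form estimator of the coalescent
## time scale, and its conjugate posterior.

#' Lineages-through-time curve of a dated tree
#'
#' Sorts the node dates of a dated tree from most recent to oldest and counts
#' the number of extant lineages on every inter-event interval (tips add a
#' lineage going back in time, coalescences remove one). Also returns the
#' coalescent weight \code{W = sum_i k_i (k_i - 1) / 2 * dt_i}.
#'
#' @param D a [datedTree()].
#' @return list with \code{times} (event dates, decreasing), \code{k}
#'   (lineages on the interval following each event, going back in time),
#'   \code{W}, and \code{n} (number of tips).
#' @export
lineageCurve <- function(D) {
  stopifnot(inherits(D, "datedTree"))
  n <- length(D$tree$tip.label)
  m <- length(D$dates)
  type <- c(rep(1, n), rep(-1, m - n))  # backward in time: +1 sample, -1 coalescence
  ord <- order(D$dates, decreasing = TRUE)
  times <- D$dates[ord]
  k <- cumsum(type[ord])
  dt <- -diff(times)
  kk <- k[-m]
  list(times = times, k = k, W = sum(kk * (kk - 1) / 2 * dt), n = n)
}

#' Coalescent log-likelihood of a dated tree (constant population size)
#'
#' Log-density of the genealogy under the heterochronous coalescent with
#' constant population size \code{ne} (in units of years, i.e. Ne times the
#' generation duration): each pair of the \code{k} extant lineages coalesces
#' at rate \code{1/ne}, so
#' \code{log p = -W/ne - (n-1)*log(ne)} with \code{W} from [lineageCurve()].
#'
#' @param D a [datedTree()].
#' @param ne coalescent time scale (\code{> 0}).
#' @return log-likelihood (scalar).
#' @export
coalLogLik <- function(D, ne) {
  if (ne <= 0) stop("ne must be positive")
  lc <- lineageCurve(D)
  -lc$W / ne - (lc$n - 1) * log(ne)
}

#' Maximum-likelihood coalescent time scale
#'
#' Closed-form maximizer of [coalLogLik()]:
#' \code{alpha_hat = sum_i k_i (k_i - 1) (t_i - t_{i+1}) / (2 (n - 1))}.
#'
#' @param D a [datedTree()] with \code{n >= 2} tips.
#' @return estimate of the coalescent time scale (years).
#' @export
mleAlpha <- function(D) {
  lc <- lineageCurve(D)
  if (lc$n < 2) stop("at least two tips are required")
  lc$W / (lc$n - 1)
}

#' Sample from the conjugate posterior of the coalescent time scale
#'
#' Under an improper inverse-gamma prior on the coalescent time scale
#' \code{alpha}, the posterior given the genealogy is
#' \code{alpha ~ InvGamma(shape = n - 1, scale = W)} with \code{W} from
#' [lineageCurve()], i.e. \code{1/alpha ~ Gamma(shape = n - 1, rate = W)}.
#'
#' @param D a [datedTree()].
#' @param n number of draws.
#' @return numeric vector of posterior draws of \code{alpha}.
#' @export
alphaPosteriorSample <- function(D, n = 1) {
  lc <- lineageCurve(D)
  if (lc$n < 2) stop("at least two tips are required")
  1 / stats::rgamma(n, shape = lc$n - 1, rate = lc$W)
}

#' Coalescent log-likelihood under a time-varying population size
#'
#' Log-density of a dated genealogy when the population size is a function
#' \code{N(t)} of calendar time: the integral of
#' \code{A(t)(A(t)-1) / (2 N(t))} over time (evaluated by adaptive quadrature
#' on each inter-event interval) plus a factor \code{1/N(c_i)} per
#' coalescence.
#'
#' @param D a [datedTree()].
#' @param Nfun vectorized function of calendar time returning the population
#'   size (years).
#' @return log-likelihood (scalar).
#' @export
coalLogLikNt <- function(D, Nfun) {
  lc <- lineageCurve(D)
  m <- length(lc$times)
  acc <- 0
  for (i in seq_len(m - 1)) {
    k <- lc$k[i]
    if (k >= 2 && lc$times[i] > lc$times[i + 1]) {
      acc <- acc - stats::integrate(function(u) k * (k - 1) / (2 * Nfun(u)),
                                    lc$times[i + 1], lc$times[i],
                                    rel.tol = 1e-10)$value
    }
  }
  n <- length(D$tree$tip.label)
  coalTimes <- D$dates[(n + 1):length(D$dates)]
  acc - sum(log(Nfun(coalTimes)))
}
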