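#' Molecular clock models
#'
#' Constructs one of the four molecular clock models giving the distribution
#' of the number of substitutions \code{l} on a branch of duration \code{d}
#' years:
#' \describe{
#'   \item{\code{poisson}}{strict clock, discrete: \code{l ~ Poisson(d*mu)}.}
#'   \item{\code{gamma}}{strict clock, continuous: \code{l ~ Gamma(shape = d*mu, scale = 1)}.}
#'   \item{\code{negbin}}{additive relaxed clock, discrete:
#'     \code{l ~ NegBin(size = d*mu/omega, prob = 1/(1+omega))}.}
#'   \item{\code{argamma}}{additive relaxed clock, continuous:
#'     \code{l ~ Gamma(shape = d*mu/(1+omega), scale = 1+omega)}.}
#' }
#' All four have mean \code{d*mu}; the variance is \code{d*mu} for the strict
#' models and \code{d*mu*(1+omega)} for the relaxed ones. A relaxed model with
#' \code{omega = 0} is its strict limit.
#'
#' @param model one of \code{"poisson"}, \code{"gamma"}, \code{"negbin"},
#'   \code{"argamma"}.
#' @param mu mean clock rate in substitutions per year (\code{> 0}).
#' @param omega relaxation parameter (\code{>= 0}); required for the relaxed
#'   families, ignored for the strict ones.
#' @return object of class \code{clockModel}.
#' @export
clockModel <- function(model = c("poisson", "gamma", "negbin", "argamma"),
                       mu, omega = NULL) {
  model <- match.arg(model)
  relaxed <- model %in% c("negbin", "argamma")
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 0) stop("mu must be a positive number")
  if (relaxed) {
    if (is.null(omega)) stop("relaxed clock models require omega")
    if (!is.numeric(omega) || length(omega) != 1 || omega < 0) stop("omega must be >= 0")
  } else omega <- NULL
  structure(list(model = model, mu = mu, omega = omega), class = "clockModel")
}

#' @export
print.clockModel <- function(x, ...) {
  nm <- c(poisson = "strict clock (Poisson)",
          gamma = "continuous strict clock (Gamma)",
          negbin = "additive relaxed clock (Negative Binomial)",
          argamma = "continuous additive relaxed clock (Gamma)")
  cat(nm[x$model], "\n  mu =", x$mu,
      if (!is.null(x$omega)) paste(" omega =", x$omega), "\n")
  invisible(x)
}

isDiscrete <- function(model) model$model %in% c("poisson", "negbin")
isRelaxed <- function(model) model$model %in% c("negbin", "argamma")

## internal: effective family after taking the omega -> 0 strict limit
effFamily <- function(model) {
  fam <- model$model
  if (isRelaxed(model) && model$omega == 0)
    fam <- if (fam == "negbin") "poisson" else "gamma"
  fam
}

checkLD <- function(l, d) {
  if (any(l < 0)) stop("substitution values must be >= 0")
  if (any(d < 0)) stop("durations must be >= 0")
}

isWhole <- function(x, tol = 1e-9) abs(x - round(x)) < tol

#' Log-probability of substitutions on a branch
#'
#' Log mass (discrete families) or log density (continuous families) of
#' observing \code{l} substitutions on a branch of duration \code{d} under a
#' clock model. A branch of zero duration carries zero substitutions with
#' probability one. Non-integer \code{l} presented to a discrete family (which
#' arises from the proportional root split) is evaluated under the
#' moment-matched continuous counterpart.
#'
#' @param model a [clockModel()].
#' @param l substitutions (vector).
#' @param d durations in years (vector, recycled against \code{l}).
#' @return vector of log-probabilities.
#' @export
branchLogProb <- function(model, l, d) {
  stopifnot(inherits(model, "clockModel"))
  n <- max(length(l), length(d))
  l <- rep_len(as.numeric(l), n); d <- rep_len(as.numeric(d), n)
  checkLD(l, d)
  fam <- effFamily(model)
  mu <- model$mu; om <- if (isRelaxed(model)) model$omega else 0
  out <- numeric(n)
  z <- d == 0
  out[z] <- ifelse(l[z] == 0, 0, -Inf)
  i <- !z
  if (any(i)) out[i] <- switch(fam,
    poisson = {
      w <- isWhole(l[i])
      r <- numeric(sum(i))
      r[w] <- stats::dpois(round(l[i][w]), d[i][w] * mu, log = TRUE)
      r[!w] <- stats::dgamma(l[i][!w], shape = d[i][!w] * mu, scale = 1, log = TRUE)
      r
    },
    gamma = stats::dgamma(l[i], shape = d[i] * mu, scale = 1, log = TRUE),
    negbin = {
      w <- isWhole(l[i])
      r <- numeric(sum(i))
      r[w] <- stats::dnbinom(round(l[i][w]), size = d[i][w] * mu / om,
                             prob = 1 / (1 + om), log = TRUE)
      r[!w] <- stats::dgamma(l[i][!w], shape = d[i][!w] * mu / (1 + om),
                             scale = 1 + om, log = TRUE)
      r
    },
    argamma = stats::dgamma(l[i], shape = d[i] * mu / (1 + om), scale = 1 + om, log = TRUE))
  out
}

#' Cumulative distribution of substitutions on a branch
#'
#' \code{P(L <= l)} under the clock model, for a branch of duration \code{d}.
#' For the discrete families this is the right-continuous CDF evaluated at
#' \code{floor(l)}; \code{P(L <= -1) = 0}.
#'
#' @inheritParams branchLogProb
#' @return vector of probabilities.
#' @export
branchCdf <- function(model, l, d) {
  stopifnot(inherits(model, "clockModel"))
  n <- max(length(l), length(d))
  l <- rep_len(as.numeric(l), n); d <- rep_len(as.numeric(d), n)
  if (any(d < 0)) stop("durations must be >= 0")
  fam <- effFamily(model)
  mu <- model$mu; om <- if (isRelaxed(model)) model$omega else 0
  out <- numeric(n)
  z <- d == 0
  out[z] <- as.numeric(l[z] >= 0)
  i <- !z
  if (any(i)) out[i] <- switch(fam,
    poisson = stats::ppois(floor(l[i] + 1e-12), d[i] * mu),
    gamma = stats::pgamma(l[i], shape = d[i] * mu, scale = 1),
    negbin = stats::pnbinom(floor(l[i] + 1e-12), size = d[i] * mu / om, prob = 1 / (1 + om)),
    argamma = stats::pgamma(l[i], shape = d[i] * mu / (1 + om), scale = 1 + om))
  out
}

#' Simulate substitutions on branches
#'
#' Draws one value per duration from the clock model distribution. Zero
#' durations give zero substitutions.
#'
#' @inheritParams branchLogProb
#' @param d durations in years (one draw per element).
#' @return vector of simulated substitution values, same length as \code{d}.
#' @export
simulateBranch <- function(model, d) {
  stopifnot(inherits(model, "clockModel"))
  d <- as.numeric(d)
  if (any(d < 0)) stop("durations must be >= 0")
  fam <- effFamily(model)
  mu <- model$mu; om <- if (isRelaxed(model)) model$omega else 0
  out <- numeric(length(d))
  i <- d > 0
  if (any(i)) out[i] <- switch(fam,
    poisson = stats::rpois(sum(i), d[i] * mu),
    gamma = stats::rgamma(sum(i), shape = d[i] * mu, scale = 1),
    negbin = stats::rnbinom(sum(i), size = d[i] * mu / om, prob = 1 / (1 + om)),
    argamma = stats::rgamma(sum(i), shape = d[i] * mu / (1 + om), scale = 1 + om))
  out
}

#' Apply a clock model to a dated tree
#'
#' Simulates an undated phylogeny from a dated one by drawing the number of
#' substitutions on every branch independently from the clock model, given the
#' branch duration.
#'
#' @param D a [datedTree()].
#' @param model a [clockModel()].
#' @return a \code{phylo} with the same topology and branch lengths in
#'   substitutions.
#' @export
applyClock <- function(D, model) {
  stopifnot(inherits(D, "datedTree"))
  L <- D$tree
  L$edge.length <- simulateBranch(model, branchDurations(D))
  L
}

#' Clock-model log-likelihood of an undated tree given a dated tree
#'
#' Sum over matched branches of the branch log-probabilities, with the
#' substitutions on the shared root branch of \code{L} split proportionally
#' between the two root-adjacent branches of \code{D}.
#'
#' @param D a [datedTree()].
#' @param L a rooted \code{phylo} with branch lengths in substitutions.
#' @param model a [clockModel()].
#' @param match optional precomputed [matchBranches()] result.
#' @return log-likelihood (scalar).
#' @export
clockLogLik <- function(D, L, model, match = NULL) {
  if (is.null(match)) match <- matchBranches(D, L)
  dur <- branchDurations(D)
  l <- effectiveSubstitutions(match, dur)
  sum(branchLogProb(model, l, dur))
}

#' Maximum-likelihood clock rate
#'
#' The closed-form estimator \code{mu_hat = sum(l) / sum(d)}: total
#' substitutions divided by total branch duration.
#'
#' @inheritParams clockLogLik
#' @return estimated clock rate (substitutions per year).
#' @export
mleMu <- function(D, L, match = NULL) {
  if (is.null(match)) match <- matchBranches(D, L)
  dur <- branchDurations(D)
  totd <- sum(dur)
  if (totd <= 0) stop("total branch duration is zero")
  totl <- sum(match$l, na.rm = TRUE) + sum(match$lx)
  totl / totd
}
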