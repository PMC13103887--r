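## Residual analysis of a dated phylogeny against its undated source tree.
##
## Each branch contributes a uniform residual u = F(l | d): the clock-model
## CDF of the observed substitutions given the branch duration. For discrete
## clock models the probability integral transform is randomized, drawing u
## uniformly on the interval (P(L <= l-1), P(L <= l)) whose width is the mass
## of the observed count, which restores exact Uniform(0,1) calibration.
## Normal residuals n = qnorm(u) are then tested against Normal(0,1) with the
## Anderson-Darling simple-hypothesis test.

UCLIP <- 1e-12

#' Uniform residuals of branch substitution counts
#'
#' @param model a [clockModel()].
#' @param l observed substitutions (vector).
#' @param d branch durations in years (vector, recycled).
#' @param randomize randomize the PIT for discrete families (default). With
#'   \code{FALSE} the midpoint of the probability interval is used instead,
#'   which is deterministic but not exactly uniform.
#' @return residuals in \code{(0,1)}, clipped to
#'   \code{[1e-12, 1 - 1e-12]}.
#' @export
uniformResiduals <- function(model, l, d, randomize = TRUE) {
  stopifnot(inherits(model, "clockModel"))
  n <- max(length(l), length(d))
  l <- rep_len(as.numeric(l), n); d <- rep_len(as.numeric(d), n)
  checkLD(l, d)
  hi <- branchCdf(model, l, d)
  u <- hi
  if (isDiscrete(model) && (is.null(model$omega) || model$omega > 0)) {
    w <- isWhole(l)  # non-integer values fall back to the continuous CDF
    if (any(w)) {
      lo <- branchCdf(model, l[w] - 1, d[w])
      u[w] <- if (randomize) stats::runif(sum(w), lo, hi[w]) else (lo + hi[w]) / 2
    }
  }
  pmin(pmax(u, UCLIP), 1 - UCLIP)
}

#' Normal residuals from uniform residuals
#'
#' Transforms uniform residuals through the standard normal quantile function,
#' giving residuals with expected distribution Normal(0,1) when the model fits.
#'
#' @param u uniform residuals in \code{(0,1)}.
#' @return numeric vector of normal residuals.
#' @export
normalResiduals <- function(u) {
  if (any(u <= 0 | u >= 1)) stop("uniform residuals must lie strictly in (0,1)")
  stats::qnorm(u)
}

## Asymptotic CDF of the Anderson-Darling statistic under a fully specified
## null (Marsaglia & Marsaglia 2004 series approximation).
adCdf <- function(z) {
  vapply(z, function(x) {
    if (x <= 0) return(0)
    if (x < 2)
      x^(-0.5) * exp(-1.2337141 / x) *
        (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
          (0.011672 - 0.00168691 * x) * x) * x) * x) * x)
    else
      exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
        (0.008056 - 0.0003146 * x) * x) * x) * x) * x))
  }, numeric(1))
}

#' Anderson-Darling simple-hypothesis test against Uniform(0,1)
#'
#' Tests a sample against the fully specified Uniform(0,1) distribution. The
#' statistic is
#' \code{A2 = -k - (1/k) * sum((2i-1) * (log z_(i) + log(1 - z_(k+1-i))))}
#' and the p-value uses the asymptotic null distribution of the statistic
#' (no small-sample correction).
#'
#' @param u sample in \code{(0,1)}.
#' @return list with \code{statistic} (A2) and \code{p.value}.
#' @export
adTestUniform <- function(u) {
  k <- length(u)
  if (k < 8) warning("Anderson-Darling test with fewer than 8 observations")
  z <- sort(pmin(pmax(u, UCLIP), 1 - UCLIP))
  i <- seq_len(k)
  A2 <- -k - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  list(statistic = A2, p.value = 1 - adCdf(A2))
}

#' Anderson-Darling simple-hypothesis test against Normal(0,1)
#'
#' Equivalent to [adTestUniform()] applied to \code{pnorm(n)}: testing the
#' normal residuals against Normal(0,1) is exactly the same test as testing
#' the uniform residuals against Uniform(0,1).
#'
#' @param n sample of normal residuals.
#' @return list with \code{statistic} (A2) and \code{p.value}.
#' @export
adTestNormal <- function(n) adTestUniform(stats::pnorm(n))

#' Residual analysis of a dated tree against an undated tree
#'
#' Computes per-branch uniform and normal residuals of the undated phylogeny
#' \code{L} given the dated phylogeny \code{D} under a clock model, and the
#' Anderson-Darling test of the residuals against their expected distribution.
#' The substitutions on the branch of \code{L} corresponding to the root split
#' of \code{D} are divided proportionally to the two root branch durations
#' before residuals are computed.
#'
#' @param D a [datedTree()].
#' @param L a rooted \code{phylo} with branch lengths in substitutions and the
#'   same leaf set as \code{D}.
#' @param model a [clockModel()] (typically the model used for dating, with
#'   its inferred parameters).
#' @param match optional precomputed [matchBranches()] result.
#' @param randomize randomize the discrete PIT (see [uniformResiduals()]).
#' @return object of class \code{residualSet}: list with \code{u}, \code{n}
#'   (per-branch residuals, in the edge order of \code{D}), \code{branch}
#'   (child node of each edge, tips labelled), \code{statistic} and
#'   \code{p.value} of the Anderson-Darling test.
#' @export
treeResiduals <- function(D, L, model, match = NULL, randomize = TRUE) {
  stopifnot(inherits(D, "datedTree"))
  if (is.null(match)) match <- matchBranches(D, L)
  dur <- branchDurations(D)
  l <- effectiveSubstitutions(match, dur)
  u <- uniformResiduals(model, l, dur, randomize = randomize)
  nres <- normalResiduals(u)
  ad <- adTestNormal(nres)
  ntip <- length(D$tree$tip.label)
  child <- D$tree$edge[, 2]
  lab <- ifelse(child <= ntip, D$tree$tip.label[pmin(child, ntip)], as.character(child))
  structure(list(u = u, n = nres, l = l, d = dur, branch = lab,
                 statistic = ad$statistic, p.value = ad$p.value),
            class = "residualSet")
}

#' @export
print.residualSet <- function(x, ...) {
  cat("Residual analysis of", length(x$u), "branches\n")
  cat("  Anderson-Darling A2 =", format(x$statistic, digits = 4),
      " p =", format(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Posterior distribution of residual p-values
#'
#' Repeats the residual analysis for every retained draw of a posterior (or
#' pseudo-posterior) sample, using that draw's dated tree and clock
#' parameters, and summarizes the resulting distribution of Anderson-Darling
#' p-values by its median and the proportion below \code{alpha}.
#'
#' @param ps a \code{posteriorSample} (see [mcmcDate()]).
#' @param L the observed undated phylogeny (branch lengths in substitutions).
#' @param family clock model family used to compute residuals; defaults to the
#'   family the posterior was inferred under.
#' @param alpha threshold for the reported proportion of small p-values.
#' @param maxDraws residual analyses are capped at this many draws,
#'   subsampled evenly.
#' @return object of class \code{posteriorPvalues}: list with the vector
#'   \code{p}, \code{median}, \code{propBelow} and \code{alpha}.
#' @export
posteriorResidualPvalues <- function(ps, L, family = NULL, alpha = 0.05,
                                     maxDraws = 1000) {
  stopifnot(inherits(ps, "posteriorSample"))
  if (is.null(family)) family <- ps$model
  nd <- nDraws(ps)
  idx <- if (nd > maxDraws) unique(round(seq(1, nd, length.out = maxDraws))) else seq_len(nd)
  match <- matchBranches(ps$tree, L)
  p <- vapply(idx, function(i) {
    dr <- getDraw(ps, i)
    m <- clockModel(family, mu = dr$mu,
                    omega = if (family %in% c("negbin", "argamma")) dr$omega)
    treeResiduals(dr$tree, L, m, match = match)$p.value
  }, numeric(1))
  structure(list(p = p, median = stats::median(p), propBelow = mean(p < alpha),
                 alpha = alpha), class = "posteriorPvalues")
}

#' @export
print.posteriorPvalues <- function(x, ...) {
  cat("Posterior distribution of residual p-values (", length(x$p), " draws)\n", sep = "")
  cat("  median p =", format(x$median, digits = 4), "\n")
  cat("  proportion below", x$alpha, "=", format(x$propBelow, digits = 4), "\n")
  invisible(x)
}
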