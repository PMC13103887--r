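## Posterior predictive checking: simulate undated phylogenies from posterior
## draws of the dated tree and clock parameters, and compare four summary
## statistics of the branch lengths (mean, variance, maximum, stemminess) with
## the observed undated phylogeny.

#' Two-sided empirical p-value
#'
#' Position of an observed statistic within a set of simulated values, with
#' the add-one rule so the p-value is strictly positive:
#' \code{p = min(1, 2 * min((1 + #\{sim <= obs\}) / (S+1),
#' (1 + #\{sim >= obs\}) / (S+1)))}.
#'
#' @param observed observed statistic (scalar).
#' @param simulated vector of simulated statistics.
#' @return p-value in \code{(0, 1]}.
#' @export
empiricalPvalue <- function(observed, simulated) {
  S <- length(simulated)
  lo <- (1 + sum(simulated <= observed)) / (S + 1)
  hi <- (1 + sum(simulated >= observed)) / (S + 1)
  min(1, 2 * min(lo, hi))
}

#' Simulate posterior predictive replicates of the summary statistics
#'
#' For each replicate, one posterior draw (dated tree and clock parameters) is
#' sampled with replacement, an undated phylogeny is simulated from it under
#' the same clock model as was used for inference, and the four branch-length
#' summary statistics are computed. A single-draw sample (a point estimate)
#' conditions every replicate on that tree and parameter set.
#'
#' @param ps a \code{posteriorSample}.
#' @param S number of replicates.
#' @param family clock model family for simulation; defaults to the family the
#'   posterior was inferred under.
#' @return an \code{S x 4} matrix with columns \code{mean}, \code{variance},
#'   \code{max}, \code{stemminess}.
#' @export
simulatePPReplicates <- function(ps, S = 1000, family = NULL) {
  stopifnot(inherits(ps, "posteriorSample"))
  if (is.null(family)) family <- ps$model
  nd <- nDraws(ps)
  idx <- if (nd == 1L) rep(1L, S) else sample.int(nd, S, replace = TRUE)
  out <- matrix(NA_real_, S, 4,
                dimnames = list(NULL, c("mean", "variance", "max", "stemminess")))
  for (s in seq_len(S)) {
    dr <- getDraw(ps, idx[s])
    m <- clockModel(family, mu = dr$mu,
                    omega = if (family %in% c("negbin", "argamma")) dr$omega)
    out[s, ] <- treeSummaryStats(applyClock(dr$tree, m))
  }
  out
}

#' Posterior predictive check of a dated phylogeny
#'
#' Compares the observed undated phylogeny with undated phylogenies simulated
#' from the posterior, via two-sided empirical p-values on four summary
#' statistics (mean, variance and maximum of branch lengths, and stemminess).
#' The four p-values are corrected for multiple testing with the
#' Benjamini-Hochberg false discovery rate and combined as the minimum
#' adjusted p-value (optionally as a harmonic-mean p-value of the raw values).
#'
#' @param ps a \code{posteriorSample} (or single point estimate wrapped with
#'   [asPosteriorSample()]).
#' @param L the observed undated phylogeny.
#' @param S number of posterior predictive replicates.
#' @param combine \code{"BH"} (default) or \code{"harmonic"}.
#' @param alpha significance level for the verdict.
#' @param family clock model family for simulation; defaults to the family the
#'   posterior was inferred under.
#' @return object of class \code{ppCheckReport}: list with \code{observed}
#'   (the four observed statistics), \code{simulated} (the replicate matrix),
#'   \code{p} (raw empirical p-values), \code{pAdjusted}, \code{combined},
#'   \code{issue} (logical verdict at \code{alpha}).
#' @export
ppCheck <- function(ps, L, S = 1000, combine = c("BH", "harmonic"),
                    alpha = 0.05, family = NULL) {
  combine <- match.arg(combine)
  obs <- treeSummaryStats(L)
  sims <- simulatePPReplicates(ps, S = S, family = family)
  p <- vapply(seq_along(obs), function(j) empiricalPvalue(obs[j], sims[, j]),
              numeric(1))
  names(p) <- names(obs)
  padj <- stats::p.adjust(p, method = "BH")
  comb <- if (combine == "BH") min(padj) else min(1, 1 / mean(1 / p))
  structure(list(observed = obs, simulated = sims, p = p, pAdjusted = padj,
                 combined = comb, issue = comb < alpha, alpha = alpha,
                 combine = combine),
            class = "ppCheckReport")
}

#' @export
print.ppCheckReport <- function(x, ...) {
  cat("Posterior predictive check (", nrow(x$simulated), " replicates)\n", sep = "")
  tab <- data.frame(observed = signif(x$observed, 5),
                    p = signif(x$p, 4), p.adjusted = signif(x$pAdjusted, 4))
  print(tab)
  cat("Combined p-value:", format(x$combined, digits = 4),
      if (x$issue) " -> issue detected" else " -> no issue detected", "\n")
  invisible(x)
}
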