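## Outlier detection: root-to-tip regression of divergence on sampling date,
## a Poisson 95% expected envelope around the regression, a date
## randomization test of temporal signal, and a per-branch clock-model tail
## test with FDR correction.

#' Root-to-tip regression
#'
#' Ordinary least squares of the root-to-tip distance (in substitutions)
#' against the tip sampling date. The slope estimates the clock rate and the
#' x-intercept the root date.
#'
#' @param L rooted \code{phylo} with branch lengths in substitutions.
#' @param dates tip dates (named vector, data.frame, CSV path, or \code{NULL}
#'   to parse from tip labels).
#' @return object of class \code{rttFit}: list with \code{slope},
#'   \code{intercept}, \code{r.squared}, \code{xIntercept} and a data frame
#'   \code{tips} (tip, date, distance).
#' @export
rootToTipRegression <- function(L, dates = NULL) {
  L <- validateTree(L)
  if (length(L$tip.label) < 3) stop("at least 3 tips are required")
  td <- resolveTipDates(L, dates)
  if (length(unique(td)) < 2) stop("all tip dates are equal: temporal signal cannot be assessed")
  dist <- node.depth.edgelength(L)[seq_along(L$tip.label)]
  fit <- stats::lm(dist ~ td)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  structure(list(slope = slope, intercept = intercept,
                 r.squared = summary(fit)$r.squared,
                 xIntercept = if (slope > 0) -intercept / slope else NA_real_,
                 tips = data.frame(tip = L$tip.label, date = unname(td),
                                   distance = dist)),
            class = "rttFit")
}

#' @export
print.rttFit <- function(x, ...) {
  cat("Root-to-tip regression over", nrow(x$tips), "tips\n")
  cat("  slope (clock rate):", format(x$slope, digits = 5), "substitutions/year\n")
  cat("  x-intercept (root date):", format(x$xIntercept, digits = 7), "\n")
  cat("  R2:", format(x$r.squared, digits = 4), "\n")
  invisible(x)
}

#' Expected envelope around the root-to-tip regression
#'
#' For each tip, the central interval of a Poisson distribution with mean
#' \code{slope * (date - xIntercept)}, i.e. the expected root-to-tip
#' divergence under a strict clock at the fitted rate. Tips whose observed
#' distance falls outside the interval are flagged.
#'
#' @param fit an [rootToTipRegression()] fit with positive slope.
#' @param level coverage level of the envelope (default 0.95).
#' @return data frame with per-tip \code{expected}, \code{lower},
#'   \code{upper} and \code{flag}.
#' @export
rttEnvelope <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rttFit"))
  if (!is.finite(fit$slope) || fit$slope <= 0)
    stop("envelope requires a positive fitted slope")
  lam <- pmax(fit$slope * (fit$tips$date - fit$xIntercept), 0)
  a <- (1 - level) / 2
  lower <- stats::qpois(a, lam)
  upper <- stats::qpois(1 - a, lam)
  data.frame(tip = fit$tips$tip, date = fit$tips$date,
             distance = fit$tips$distance, expected = lam,
             lower = lower, upper = upper,
             flag = fit$tips$distance < lower | fit$tips$distance > upper)
}

#' Date randomization test of temporal signal
#'
#' Permutes the tip sampling dates and recomputes the regression statistic;
#' the p-value is \code{(1 + #\{permuted >= observed\}) / (B + 1)}.
#'
#' @param L rooted \code{phylo} with branch lengths in substitutions.
#' @param dates tip dates (see [rootToTipRegression()]).
#' @param B number of permutations (default 10000).
#' @param statistic \code{"rsq"} (default, the regression R-squared) or
#'   \code{"slope"}.
#' @return list with \code{p.value}, \code{observed} and the vector
#'   \code{permuted}.
#' @export
dateRandomizationTest <- function(L, dates = NULL, B = 10000,
                                  statistic = c("rsq", "slope")) {
  statistic <- match.arg(statistic)
  L <- validateTree(L)
  td <- resolveTipDates(L, dates)
  dist <- node.depth.edgelength(L)[seq_along(L$tip.label)]
  if (stats::sd(dist) == 0) {
    statFun <- function(x) 0   # no divergence variation: nothing to correlate
  } else if (statistic == "rsq") {
    statFun <- function(x) { r <- stats::cor(dist, x); if (is.na(r)) 0 else r^2 }
  } else {
    statFun <- function(x) {
      v <- stats::var(x)
      if (v == 0) 0 else stats::cov(dist, x) / v
    }
  }
  obs <- statFun(td)
  perm <- vapply(seq_len(B), function(b) statFun(sample(td)), numeric(1))
  list(p.value = (1 + sum(perm >= obs)) / (B + 1), observed = obs,
       permuted = perm, statistic = statistic)
}

#' Per-branch outlier test under a fitted clock model
#'
#' For each branch of the dated tree, a two-sided tail probability of the
#' observed number of substitutions under the fitted clock model given the
#' branch duration: \code{p = min(1, 2*min(P(L <= l), P(L >= l)))}. P-values
#' are Benjamini-Hochberg adjusted and branches flagged at \code{q < alpha}.
#'
#' @param D a [datedTree()].
#' @param L the undated phylogeny (substitutions).
#' @param model fitted [clockModel()].
#' @param alpha FDR threshold for flagging (default 0.05).
#' @param match optional precomputed [matchBranches()] result.
#' @return object of class \code{outlierReport}: data frame with one row per
#'   branch (\code{branch}, \code{l}, \code{d}, \code{p}, \code{q},
#'   \code{flag}).
#' @export
branchOutlierTest <- function(D, L, model, alpha = 0.05, match = NULL) {
  stopifnot(inherits(D, "datedTree"))
  if (is.null(match)) match <- matchBranches(D, L)
  dur <- branchDurations(D)
  l <- effectiveSubstitutions(match, dur)
  lo <- branchCdf(model, l, dur)                # P(L <= l)
  hi <- if (isDiscrete(model) && all(isWhole(l))) {
    1 - branchCdf(model, l - 1, dur)            # P(L >= l), discrete
  } else {
    up <- 1 - branchCdf(model, l, dur)
    if (isDiscrete(model)) {                    # mixed integer / root-split values
      w <- isWhole(l)
      up[w] <- 1 - branchCdf(model, l[w] - 1, dur[w])
    }
    up
  }
  p <- pmin(1, 2 * pmin(lo, hi))
  q <- stats::p.adjust(p, method = "BH")
  ntip <- length(D$tree$tip.label)
  child <- D$tree$edge[, 2]
  lab <- ifelse(child <= ntip, D$tree$tip.label[pmin(child, ntip)], as.character(child))
  out <- data.frame(branch = lab, isTip = child <= ntip, l = l, d = dur,
                    p = p, q = q, flag = q < alpha)
  class(out) <- c("outlierReport", "data.frame")
  out
}

#' @export
print.outlierReport <- function(x, ...) {
  cat("Per-branch outlier test:", sum(x$flag), "of", nrow(x),
      "branches flagged\n")
  if (any(x$flag)) print.data.frame(x[x$flag, ], row.names = FALSE)
  invisible(x)
}
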