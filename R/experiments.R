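## Replicate experiment harness: simulate many datasets, date each one under
## stated conditions (root date and/or clock rate given or free), run the
## posterior predictive and residual diagnostics, and test the false-positive
## counts against the nominal 5% rate with an exact binomial test.

#' Exact binomial test of a diagnostic count
#'
#' Two-sided exact binomial test of \code{count} detections out of \code{R}
#' replicates against the nominal rate, starred when \code{p < level}.
#'
#' @param count number of replicates where the diagnostic fired.
#' @param R number of replicates.
#' @param rate nominal rate under calibration (default 0.05).
#' @param level significance threshold for the star (default 0.01).
#' @return list with \code{p.value}, \code{star} (logical) and
#'   \code{direction} (\code{"over"}, \code{"under"} or \code{"none"}).
#' @export
binomialStar <- function(count, R, rate = 0.05, level = 0.01) {
  if (count < 0 || count > R) stop("count must lie in [0, R]")
  p <- stats::binom.test(count, R, p = rate)$p.value
  list(p.value = p, star = p < level,
       direction = if (count > R * rate) "over" else if (count < R * rate) "under" else "none")
}

#' Replicate diagnostic experiment
#'
#' Simulates \code{R} datasets, dates each with the internal MCMC engine under
#' the requested conditions, applies the posterior predictive check and the
#' residual analysis, and counts how often each diagnostic fires at level
#' \code{alpha}. For the correct-model scenario the counts estimate the
#' false-positive rate and are tested against \code{alpha} with
#' [binomialStar()]; for the misspecified scenario (relaxed-clock data fitted
#' with a strict clock) they estimate the detection power.
#'
#' @param R number of replicate datasets.
#' @param scenario \code{"correct"}: strict-clock data fitted with the strict
#'   clock; \code{"misspecified"}: additive-relaxed data fitted with the
#'   strict clock.
#' @param conditions character subset of \code{"neither"}, \code{"root"},
#'   \code{"rate"}, \code{"both"}: which of the true root date and clock rate
#'   are supplied to the dating engine.
#' @param n,tmin,tmax,ne,mu,omega simulation settings (see
#'   [simulateDataset()]).
#' @param iters MCMC sweeps per fit.
#' @param S posterior predictive replicates per fit.
#' @param alpha diagnostic significance level.
#' @param seed master seed; per-replicate seeds are derived from it and
#'   recorded in the result.
#' @return object of class \code{experimentResult}: list with \code{counts}
#'   (conditions x tests matrix of detections), \code{R}, \code{binomial}
#'   (per-cell [binomialStar()] p-values and stars), \code{failures}
#'   (replicate-level errors, counted separately) and \code{seeds}.
#' @export
runReplicates <- function(R = 20, scenario = c("correct", "misspecified"),
                          conditions = c("neither", "root", "rate", "both"),
                          n = 50, tmin = 2010, tmax = 2020, ne = 1, mu = 10,
                          omega = 5, iters = 400, S = 300, alpha = 0.05,
                          seed = 1) {
  scenario <- match.arg(scenario)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (R < 1) stop("R must be >= 1")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, R)
  tests <- c("PPcheck", "Residuals")
  counts <- matrix(0L, length(conditions), 2,
                   dimnames = list(conditions, tests))
  failures <- character(0)
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    sim <- simulateDataset(if (scenario == "correct") "constant" else "relaxed",
                           n = n, tmin = tmin, tmax = tmax, ne = ne,
                           mu = mu, omega = omega)
    for (cond in conditions) {
      fixed <- list()
      if (cond %in% c("root", "both")) fixed$rootDate <- sim$truth$rootDate
      if (cond %in% c("rate", "both")) fixed$mu <- mu
      res <- tryCatch({
        ps <- mcmcDate(sim$undated, sim$dates, model = "poisson",
                       iters = iters, fixed = fixed, maxDraws = 200)
        pp <- ppCheck(ps, sim$undated, S = S, alpha = alpha)
        rs <- posteriorResidualPvalues(ps, sim$undated, maxDraws = 200)
        c(pp$issue, rs$median < alpha)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("replicate %d, condition %s: %s",
                                        r, cond, conditionMessage(res)))
      } else {
        counts[cond, ] <- counts[cond, ] + res
      }
    }
  }
  binomial <- apply(counts, c(1, 2), function(ct) binomialStar(ct, R, rate = alpha))
  structure(list(counts = counts, R = R, scenario = scenario, alpha = alpha,
                 binomial = binomial, failures = failures, seeds = seeds),
            class = "experimentResult")
}

#' @export
print.experimentResult <- function(x, ...) {
  cat("Replicate experiment (", x$scenario, " model, R = ", x$R, ")\n", sep = "")
  disp <- matrix(as.character(x$counts), nrow(x$counts), ncol(x$counts),
                 dimnames = dimnames(x$counts))
  for (i in seq_len(nrow(disp))) for (j in seq_len(ncol(disp))) {
    if (x$binomial[[i, j]]$star)
      disp[i, j] <- paste0(disp[i, j], "*")
  }
  print(disp, quote = FALSE)
  if (length(x$failures)) cat(length(x$failures), "replicate failure(s)\n")
  invisible(x)
}
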