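## Bayesian dating engine: Metropolis-Hastings over internal node dates, the
## clock rate mu, the relaxation omega and the coalescent time scale Ne, with
## target distribution
##   coalescent(dates | Ne) * clock(L | dates, mu, omega) * priors(mu, omega, Ne)
## on the fixed topology of the input undated tree. One iteration is a sweep:
## every internal node date is updated once (random order) followed by each
## free parameter; proposal steps adapt during burn-in towards ~25% acceptance.

## internal: unvalidated clockModel for hot loops
quickModel <- function(fam, mu, om) {
  structure(list(model = fam, mu = mu,
                 omega = if (fam %in% c("negbin", "argamma")) om),
            class = "clockModel")
}

#' Bayesian dating of an undated phylogeny
#'
#' Samples dated trees and clock/coalescent parameters from the posterior
#' given a rooted undated phylogeny (branch lengths in substitutions) and the
#' tip sampling dates, under one of the four clock models and a constant-size
#' heterochronous coalescent prior on node dates. Priors: \code{mu ~
#' Exponential} with mean the root-to-tip regression slope, \code{omega ~
#' Exponential(1)}, and an improper \code{1/Ne} prior on \code{Ne}.
#'
#' @param L rooted binary \code{phylo} with branch lengths in substitutions.
#' @param dates tip dates (named vector, data frame, CSV path or \code{NULL}
#'   to parse from tip labels).
#' @param model clock model family: \code{"poisson"}, \code{"gamma"},
#'   \code{"negbin"} or \code{"argamma"}.
#' @param iters number of MCMC sweeps.
#' @param burnin fraction of sweeps discarded.
#' @param maxDraws retained draws are thinned to at most this many.
#' @param seed optional RNG seed for a reproducible run.
#' @param fixed named list fixing parameters: any of \code{mu}, \code{omega},
#'   \code{ne}, \code{rootDate} (fixing the root date pins the root node).
#' @param init optional initial node date vector (length Ntip + Nnode).
#' @param priorMuMean mean of the exponential prior on \code{mu}; default is
#'   the root-to-tip regression slope (floored at 1e-6).
#' @return a \code{posteriorSample}; the element \code{loglik} holds the clock
#'   log-likelihood of each retained draw (used by [dic()]), and attribute
#'   \code{"acceptance"} the per-move acceptance rates.
#' @export
mcmcDate <- function(L, dates = NULL, model = c("poisson", "gamma", "negbin", "argamma"),
                     iters = 2000, burnin = 0.5, maxDraws = 1000, seed = NULL,
                     fixed = list(), init = NULL, priorMuMean = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  L <- validateTree(L)
  if (!ape::is.binary(L)) stop("the dating engine requires a binary tree")
  td <- resolveTipDates(L, dates)
  n <- length(L$tip.label)
  m <- n + L$Nnode
  root <- n + 1L
  e1 <- L$edge[, 1]; e2 <- L$edge[, 2]
  bm <- selfMatch(L)
  l <- L$edge.length
  rootEdges <- bm$rootEdges
  lx <- bm$lx
  relaxed <- model %in% c("negbin", "argamma")
  span <- max(diff(range(td)), 1)

  ## node adjacency
  parentEdge <- rep(NA_integer_, m); parentEdge[e2] <- seq_along(e2)
  childEdges <- split(seq_along(e1), factor(e1, levels = seq_len(m)))
  type <- c(rep(1, n), rep(-1, m - n))

  coalW <- function(dt) {
    ord <- order(dt, decreasing = TRUE)
    k <- cumsum(type[ord])
    kk <- k[-m]
    sum(kk * (kk - 1) / 2 * (-diff(dt[ord])))
  }

  ## clock log-likelihood of a subset of edges (root pair always recomputed
  ## together because the substitution split depends on both durations)
  lpEdges <- function(idx, dt, mod) {
    dur <- dt[e2[idx]] - dt[e1[idx]]
    if (any(dur < 0)) return(-Inf)
    lv <- l[idx]
    if (!is.null(rootEdges)) {
      ir <- match(rootEdges, idx)
      if (!anyNA(ir)) {
        lv[ir] <- splitRootSubstitutions(lx, dur[ir[1]], dur[ir[2]])
      }
    }
    sum(branchLogProb(mod, lv, dur))
  }
  allEdges <- seq_along(e1)

  ## initialization
  rtSlope <- tryCatch(max(rootToTipRegression(L, td)$slope, 1e-6), error = function(e) 1e-6)
  mu0 <- if (!is.null(priorMuMean)) priorMuMean else max(rtSlope, 1e-6)
  dt <- numeric(m)
  dt[seq_len(n)] <- td
  if (!is.null(init)) {
    if (length(init) != m) stop("init must have one date per node")
    dt <- as.numeric(init)
  } else {
    depth <- node.depth.edgelength(L)
    r0 <- min(td - depth[seq_len(n)] / rtSlope)
    dt[(n + 1):m] <- r0 + depth[(n + 1):m] / rtSlope
  }
  ## enforce parent < child everywhere, processing children before parents
  eps <- 1e-4 * span
  internals <- (n + 1):m
  pre <- ape::reorder.phylo(L, "cladewise")
  ordPre <- unique(pre$edge[, 1])       # parents before children
  ordPost <- rev(ordPre)                # children before parents
  for (nd in ordPost) {
    ch <- e2[childEdges[[nd]]]
    dt[nd] <- min(dt[nd], min(dt[ch]) - eps)
  }
  if (!is.null(fixed$rootDate)) {
    fr <- fixed$rootDate
    if (fr > min(td) + 1e-12) stop("fixed root date is younger than the most ancient tip")
    ## squeeze internal dates into (rootDate, tip dates) keeping strict order
    eps2 <- max(min(eps, (min(td) - fr) / (m + 2)), 0)
    for (nd in ordPre) {
      lo <- if (nd == root) fr else dt[e1[parentEdge[nd]]] + eps2
      dt[nd] <- max(dt[nd], lo)
    }
    for (nd in setdiff(ordPost, root)) {
      ch <- e2[childEdges[[nd]]]
      dt[nd] <- min(dt[nd], min(dt[ch]) - eps2)
    }
    dt[root] <- fr
    ch <- e2[childEdges[[root]]]
    if (fr > min(dt[ch])) stop("could not initialize node dates with the fixed root date")
  }

  durAll <- dt[e2] - dt[e1]
  mu <- if (!is.null(fixed$mu)) fixed$mu else
    max((sum(bm$l, na.rm = TRUE) + sum(lx)) / sum(durAll), 1e-6)
  om <- if (!relaxed) 0 else if (!is.null(fixed$omega)) fixed$omega else 1
  W <- coalW(dt)
  ne <- if (!is.null(fixed$ne)) fixed$ne else max(W / (n - 1), 1e-6)

  mod <- quickModel(model, mu, om)
  clockCur <- lpEdges(allEdges, dt, mod)
  if (!is.finite(clockCur)) stop("initial clock likelihood is not finite")
  coalCur <- -W / ne - (n - 1) * log(ne)

  freeNodes <- if (is.null(fixed$rootDate)) internals else setdiff(internals, root)
  nburn <- floor(iters * burnin)
  keepIdx <- seq(nburn + 1L, iters)
  thin <- max(1L, ceiling(length(keepIdx) / maxDraws))
  keepIdx <- keepIdx[seq(thin, length(keepIdx), by = thin)]
  nkeep <- length(keepIdx)
  outDates <- matrix(NA_real_, nkeep, m)
  outMu <- outOm <- outNe <- outCl <- outCo <- numeric(nkeep)
  kp <- 0L

  sNode <- span / 20; sMu <- 0.2; sOm <- 0.3; sNe <- 0.5
  acc <- c(node = 0, mu = 0, omega = 0, ne = 0)
  try_ <- c(node = 0, mu = 0, omega = 0, ne = 0)
  accTot <- acc; tryTot <- try_

  logPriorMu <- function(x) stats::dexp(x, rate = 1 / mu0, log = TRUE)

  for (it in seq_len(iters)) {
    for (nd in sample(freeNodes)) {
      try_["node"] <- try_["node"] + 1
      newd <- dt[nd] + stats::rnorm(1, 0, sNode)
      ch <- e2[childEdges[[nd]]]
      if (newd > min(dt[ch])) next
      if (nd != root && newd < dt[e1[parentEdge[nd]]]) next
      aff <- c(if (nd != root) parentEdge[nd], childEdges[[nd]])
      if (!is.null(rootEdges) && any(rootEdges %in% aff)) aff <- union(aff, rootEdges)
      oldLp <- lpEdges(aff, dt, mod)
      dt2 <- dt; dt2[nd] <- newd
      newLp <- lpEdges(aff, dt2, mod)
      W2 <- coalW(dt2)
      logr <- (newLp - oldLp) + (-(W2 - W) / ne)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        dt <- dt2; W <- W2
        clockCur <- clockCur + (newLp - oldLp)
        coalCur <- -W / ne - (n - 1) * log(ne)
        acc["node"] <- acc["node"] + 1
      }
    }
    if (is.null(fixed$mu)) {
      try_["mu"] <- try_["mu"] + 1
      mu2 <- mu * exp(sMu * stats::rnorm(1))
      mod2 <- quickModel(model, mu2, om)
      new <- lpEdges(allEdges, dt, mod2)
      logr <- new - clockCur + logPriorMu(mu2) - logPriorMu(mu) + log(mu2 / mu)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        mu <- mu2; mod <- mod2; clockCur <- new; acc["mu"] <- acc["mu"] + 1
      }
    }
    if (relaxed && is.null(fixed$omega)) {
      try_["omega"] <- try_["omega"] + 1
      om2 <- om * exp(sOm * stats::rnorm(1))
      mod2 <- quickModel(model, mu, om2)
      new <- lpEdges(allEdges, dt, mod2)
      logr <- new - clockCur + stats::dexp(om2, 1, log = TRUE) -
        stats::dexp(om, 1, log = TRUE) + log(om2 / om)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        om <- om2; mod <- mod2; clockCur <- new; acc["omega"] <- acc["omega"] + 1
      }
    }
    if (is.null(fixed$ne)) {
      try_["ne"] <- try_["ne"] + 1
      ne2 <- ne * exp(sNe * stats::rnorm(1))
      newCo <- -W / ne2 - (n - 1) * log(ne2)
      logr <- newCo - coalCur - log(ne2) + log(ne) + log(ne2 / ne)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        ne <- ne2; coalCur <- newCo; acc["ne"] <- acc["ne"] + 1
      }
    }
    ## adapt proposal steps during burn-in
    if (it <= nburn && it %% 10 == 0) {
      ad <- 2 / sqrt(it)
      if (try_["node"] > 0) sNode <- sNode * exp(ad * (acc["node"] / try_["node"] - 0.25))
      if (try_["mu"] > 0) sMu <- sMu * exp(ad * (acc["mu"] / try_["mu"] - 0.25))
      if (try_["omega"] > 0) sOm <- sOm * exp(ad * (acc["omega"] / try_["omega"] - 0.25))
      if (try_["ne"] > 0) sNe <- sNe * exp(ad * (acc["ne"] / try_["ne"] - 0.25))
      accTot <- accTot + acc; tryTot <- tryTot + try_
      acc[] <- 0; try_[] <- 0
    }
    if (it %% 200 == 0) clockCur <- lpEdges(allEdges, dt, mod)  # guard against drift
    if (kp < nkeep && it == keepIdx[kp + 1L]) {
      kp <- kp + 1L
      outDates[kp, ] <- dt
      outMu[kp] <- mu; outOm[kp] <- if (relaxed) om else NA_real_
      outNe[kp] <- ne
      outCl[kp] <- lpEdges(allEdges, dt, mod)
      outCo[kp] <- coalCur
    }
  }
  accTot <- accTot + acc; tryTot <- tryTot + try_
  ps <- newPosteriorSample(L, outDates, outMu, outOm, outNe, outCl, outCo,
                           model = model, tipDates = td)
  attr(ps, "acceptance") <- ifelse(tryTot > 0, accTot / tryTot, NA)
  attr(ps, "settings") <- list(iters = iters, burnin = burnin, thin = thin,
                               fixed = fixed, priorMuMean = mu0)
  ps
}

#' Deviance information criterion of a dating fit
#'
#' \code{DIC = mean(deviance) + pD} with the effective number of parameters
#' \code{pD = var(deviance)/2} and \code{deviance = -2 * clock log-likelihood}
#' of each retained posterior draw.
#'
#' @param ps a \code{posteriorSample} from [mcmcDate()] with at least 50
#'   draws.
#' @return the DIC (scalar).
#' @export
dic <- function(ps) {
  stopifnot(inherits(ps, "posteriorSample"))
  if (nDraws(ps) < 50) stop("at least 50 posterior draws are required for the DIC")
  if (anyNA(ps$loglik)) stop("posterior sample carries no log-likelihoods")
  dev <- -2 * ps$loglik
  mean(dev) + stats::var(dev) / 2
}

#' Point-estimate dating of an undated phylogeny
#'
#' Point-estimate counterpart of [mcmcDate()]: cyclic one-dimensional
#' optimization of the internal node dates, maximizing the clock
#' log-likelihood plus (by default) the constant-size coalescent log-density
#' of the node dates. The clock rate and coalescent time scale are profiled by
#' their conditional closed-form maximizers (\code{sum(l)/sum(d)} and
#' [mleAlpha()]) between sweeps. The coalescent penalty matters: the
#' unpenalized clock likelihood is maximized by collapsing low-count branches
#' to zero duration and inflating the rate, a degenerate overfit that
#' penalized dating tools avoid; \code{penalized = FALSE} exposes that raw
#' optimum (with the rate then held at the root-to-tip regression slope).
#'
#' @inheritParams mcmcDate
#' @param mu clock rate; profiled when \code{NULL} (penalized fit) or set to
#'   the root-to-tip regression slope (unpenalized fit).
#' @param omega relaxation parameter for relaxed families (not profiled).
#' @param penalized include the coalescent log-density of the node dates in
#'   the objective (default \code{TRUE}).
#' @param warmStart run a short MCMC first and start the optimization from its
#'   highest-density draw; cyclic ascent from a regression-based start can
#'   wedge whole subtrees in poor local optima that single-node moves cannot
#'   escape (default \code{TRUE}; uses the session RNG).
#' @param maxSweeps maximum number of optimization sweeps.
#' @param tol convergence tolerance on the objective.
#' @return list of class \code{mlDating} with \code{tree} (a [datedTree()]),
#'   \code{mu}, \code{ne} and \code{loglik} (the clock log-likelihood at the
#'   optimum).
#' @export
mlDate <- function(L, dates = NULL, model = c("poisson", "gamma", "negbin", "argamma"),
                   mu = NULL, omega = 1, penalized = TRUE, warmStart = TRUE,
                   maxSweeps = 50, tol = 1e-6) {
  model <- match.arg(model)
  L <- validateTree(L)
  if (!ape::is.binary(L)) stop("ML dating requires a binary tree")
  td <- resolveTipDates(L, dates)
  n <- length(L$tip.label)
  m <- n + L$Nnode
  root <- n + 1L
  e1 <- L$edge[, 1]; e2 <- L$edge[, 2]
  bm <- selfMatch(L)
  l <- L$edge.length
  rootEdges <- bm$rootEdges; lx <- bm$lx
  parentEdge <- rep(NA_integer_, m); parentEdge[e2] <- seq_along(e2)
  childEdges <- split(seq_along(e1), factor(e1, levels = seq_len(m)))
  span <- max(diff(range(td)), 1)
  relaxed <- model %in% c("negbin", "argamma")

  lpEdges <- function(idx, dt, mod) {
    dur <- dt[e2[idx]] - dt[e1[idx]]
    if (any(dur < 0)) return(-Inf)
    lv <- l[idx]
    if (!is.null(rootEdges)) {
      ir <- match(rootEdges, idx)
      if (!anyNA(ir)) lv[ir] <- splitRootSubstitutions(lx, dur[ir[1]], dur[ir[2]])
    }
    sum(branchLogProb(mod, lv, dur))
  }
  allEdges <- seq_along(e1)

  rtSlope <- tryCatch(max(rootToTipRegression(L, td)$slope, 1e-6), error = function(e) 1e-6)
  depth <- node.depth.edgelength(L)
  dt <- numeric(m)
  dt[seq_len(n)] <- td
  r0 <- min(td - depth[seq_len(n)] / rtSlope)
  dt[(n + 1):m] <- r0 + depth[(n + 1):m] / rtSlope
  eps <- 1e-4 * span
  internals <- (n + 1):m
  pre <- ape::reorder.phylo(L, "cladewise")
  ordInt <- rev(unique(pre$edge[, 1]))  # children before parents
  for (nd in ordInt) {
    ch <- e2[childEdges[[nd]]]
    dt[nd] <- min(dt[nd], min(dt[ch]) - eps)
  }
  type <- c(rep(1, n), rep(-1, m - n))
  coalW <- function(dtv) {
    ord <- order(dtv, decreasing = TRUE)
    k <- cumsum(type[ord])
    kk <- k[-m]
    sum(kk * (kk - 1) / 2 * (-diff(dtv[ord])))
  }
  muFree <- is.null(mu)
  if (muFree) {
    mu <- if (penalized) max(sum(l) / sum(dt[e2] - dt[e1]), 1e-6) else rtSlope
  }
  if (warmStart) {
    ws <- mcmcDate(L, td, model = model, iters = 400, burnin = 0.25,
                   maxDraws = 300, fixed = list(mu = mu, omega = if (relaxed) omega),
                   init = dt)
    best <- which.max(ws$loglik + ws$coalLoglik)
    dt <- ws$dates[best, ]
  }
  ne <- max(coalW(dt) / (n - 1), 1e-9)
  mod <- quickModel(model, mu, if (relaxed) omega else 0)
  runSweeps <- function(dt, ne, mu, mod, withPenalty) {
    objective <- function(dtv) lpEdges(allEdges, dtv, mod) +
      (1 - n) * (1 + log(coalW(dtv) / (n - 1)))  # coalescent term at profiled Ne
    cur <- if (withPenalty) objective(dt) else lpEdges(allEdges, dt, mod)
    for (sweep in seq_len(maxSweeps)) {
      for (nd in ordInt) {
        ch <- e2[childEdges[[nd]]]
        upper <- min(dt[ch])
        lower <- if (nd == root) upper - 5 * span else dt[e1[parentEdge[nd]]]
        if (upper - lower < 1e-12) next
        aff <- c(if (nd != root) parentEdge[nd], childEdges[[nd]])
        if (!is.null(rootEdges) && any(rootEdges %in% aff)) aff <- union(aff, rootEdges)
        f <- if (withPenalty) {
          function(x) {
            dt2 <- dt; dt2[nd] <- x
            lpEdges(aff, dt2, mod) - coalW(dt2) / ne
          }
        } else {
          function(x) { dt2 <- dt; dt2[nd] <- x; lpEdges(aff, dt2, mod) }
        }
        opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = 1e-7 * span)
        if (opt$objective > f(dt[nd])) dt[nd] <- opt$maximum
      }
      if (withPenalty) {
        ne <- max(coalW(dt) / (n - 1), 1e-9)
        if (muFree) {
          mu <- max(sum(l) / sum(dt[e2] - dt[e1]), 1e-6)
          mod <- quickModel(model, mu, if (relaxed) omega else 0)
        }
      }
      new <- if (withPenalty) objective(dt) else lpEdges(allEdges, dt, mod)
      if (new - cur < tol) { cur <- new; break }
      cur <- new
    }
    list(dt = dt, ne = ne, mu = mu, mod = mod)
  }
  ## penalized pass first in all cases: it provides a well-structured tree from
  ## which the unpenalized polish reaches a proper (overfitted) optimum rather
  ## than a wedged local one
  st <- runSweeps(dt, ne, mu, mod, withPenalty = TRUE)
  if (!penalized) st <- runSweeps(st$dt, st$ne, st$mu, st$mod, withPenalty = FALSE)
  dt <- st$dt; ne <- st$ne; mu <- st$mu; mod <- st$mod
  structure(list(tree = datedTree(L, dt), mu = mu, ne = ne,
                 loglik = lpEdges(allEdges, dt, mod), model = model),
            class = "mlDating")
}

#' @export
print.mlDating <- function(x, ...) {
  cat("Maximum-likelihood dated tree (", x$model, " clock)\n", sep = "")
  cat("  mu =", format(x$mu, digits = 5), " log-likelihood =",
      format(x$loglik, digits = 8), "\n")
  n <- length(x$tree$tree$tip.label)
  cat("  root date:", format(x$tree$dates[n + 1], digits = 7), "\n")
  invisible(x)
}

#' Pseudo-posterior sample centered on a point-estimate dated tree
#'
#' Residual diagnostics computed directly on a maximum-likelihood dated tree
#' are underdispersed because the point estimate overfits the branch
#' durations. This generates an approximate posterior sample centered on the
#' point estimate instead: the input tree is rescaled to substitution units
#' (durations times the clock rate), and a short MCMC is run over node dates
#' only, under the continuous strict clock with the clock rate fixed at its
#' estimate and the coalescent time scale fixed at its closed-form estimate.
#'
#' @param D point-estimate [datedTree()].
#' @param L the undated phylogeny the estimate was derived from.
#' @param mu clock rate estimate; default is [mleMu()] on \code{D} and
#'   \code{L}.
#' @param ne coalescent time scale; default is [mleAlpha()] on \code{D}.
#' @param iters,burnin,maxDraws,seed MCMC settings (see [mcmcDate()]).
#' @return a \code{posteriorSample} under the continuous strict clock, with
#'   \code{mu} constant at its estimate.
#' @export
pseudoPosterior <- function(D, L, mu = NULL, ne = NULL, iters = 3000,
                            burnin = 0.5, maxDraws = 1000, seed = NULL) {
  stopifnot(inherits(D, "datedTree"))
  bm <- matchBranches(D, L)
  if (is.null(mu)) mu <- mleMu(D, L, bm)
  if (is.null(ne)) ne <- mleAlpha(D)
  R <- D$tree
  R$edge.length <- pmax(branchDurations(D) * mu, 1e-3)
  n <- length(R$tip.label)
  td <- stats::setNames(D$dates[seq_len(n)], R$tip.label)
  mcmcDate(R, td, model = "gamma", iters = iters, burnin = burnin,
           maxDraws = maxDraws, seed = seed,
           fixed = list(mu = mu, ne = ne), init = D$dates)
}

#' Conjugate posterior of a branch duration in the iid toy model
#'
#' In the idealized model where branch durations are iid
#' \code{d ~ Gamma(shape = k, scale = theta)} and substitutions are
#' \code{l | d ~ Poisson(d * mu)} with known rate, the posterior of \code{d}
#' is \code{Gamma(shape = k + l, scale = theta / (1 + theta * mu))} by
#' Gamma-Poisson conjugacy. Residuals of \code{l} against posterior draws of
#' \code{d} are exactly Uniform(0,1), whereas residuals against the
#' maximum-likelihood estimate \code{d_hat = l / mu} are underdispersed; this
#' is the motivating case for [pseudoPosterior()].
#'
#' @param k,theta prior shape and scale (\code{> 0}).
#' @param mu known clock rate (\code{> 0}).
#' @param l observed substitution count (integer \code{>= 0}).
#' @return list with posterior \code{shape} and \code{scale}.
#' @export
conjugateToy <- function(k, theta, mu, l) {
  if (k <= 0 || theta <= 0 || mu <= 0) stop("k, theta and mu must be positive")
  if (l < 0 || !isWhole(l)) stop("l must be a non-negative integer")
  list(shape = k + l, scale = theta / (1 + theta * mu))
}
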