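## Simulation of dated phylogenies under the heterochronous coalescent with
## constant or time-varying population size, clonal-expansion trajectories,
## structured populations, and outlier injection on undated trees.

#' Uniformly distributed sampling dates
#'
#' @param n number of tips.
#' @param tmin,tmax range of sampling dates (decimal years).
#' @return named numeric vector of dates (tips \code{t1..tn}).
#' @export
uniformDates <- function(n, tmin = 2010, tmax = 2020) {
  stats::setNames(stats::runif(n, tmin, tmax), paste0("t", seq_len(n)))
}

## internal: assemble a datedTree from a completed coalescent simulation
buildCoalTree <- function(labels, nodeDates, edges) {
  n <- length(labels)
  phy <- list(edge = edges, edge.length = nodeDates[edges[, 2]] - nodeDates[edges[, 1]],
              tip.label = labels, Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  datedTree(phy, nodeDates)
}

## internal: generic heterochronous coalescent simulation engine.
## waitFun(t, k, tStop) returns the coalescence time (going backward from t
## with k lineages) or NULL if the boundary tStop is reached first.
simCoalEngine <- function(dates, waitFun) {
  n <- length(dates)
  if (n < 2) stop("at least two tips are required")
  labels <- names(dates)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ord <- order(dates, decreasing = TRUE)
  nodeDates <- numeric(2 * n - 1)
  nodeDates[seq_len(n)] <- dates
  edges <- matrix(0L, 2 * n - 2, 2)
  nextInternal <- 2L * n - 1L
  eRow <- 0L
  active <- integer(0)
  ptr <- 1L
  t <- dates[ord[1]]
  repeat {
    while (ptr <= n && dates[ord[ptr]] >= t - 1e-12) {
      active <- c(active, ord[ptr]); ptr <- ptr + 1L
    }
    k <- length(active)
    if (k < 2) {
      if (ptr > n) break
      t <- dates[ord[ptr]]
      next
    }
    tStop <- if (ptr <= n) dates[ord[ptr]] else -Inf
    tc <- waitFun(t, k, tStop)
    if (is.null(tc)) { t <- tStop; next }
    t <- tc
    pick <- sample.int(k, 2)
    nd <- nextInternal; nextInternal <- nextInternal - 1L
    nodeDates[nd] <- t
    edges[eRow + 1L, ] <- c(nd, active[pick[1]])
    edges[eRow + 2L, ] <- c(nd, active[pick[2]])
    eRow <- eRow + 2L
    active <- c(active[-pick], nd)
    if (length(active) == 1L && ptr > n) break
  }
  buildCoalTree(labels, nodeDates, edges)
}

#' Simulate a dated tree under the constant-size heterochronous coalescent
#'
#' Going back in time, with \code{k} extant lineages the waiting time to the
#' next coalescence is exponential with rate \code{k(k-1)/(2*ne)}, interleaved
#' with the sampling events of the tips.
#'
#' @param dates tip sampling dates (named numeric vector; names become tip
#'   labels, defaulting to \code{t1..tn}).
#' @param ne coalescent time scale (Ne times generation duration, years).
#' @return a [datedTree()].
#' @export
simCoalescent <- function(dates, ne = 1) {
  if (ne <= 0) stop("ne must be positive")
  simCoalEngine(dates, function(t, k, tStop) {
    tc <- t - stats::rexp(1, rate = k * (k - 1) / (2 * ne))
    if (tc < tStop) NULL else tc
  })
}

#' Logistic clonal-expansion population size
#'
#' Population trajectory of a clonal expansion starting at date \code{s} with
#' size zero, reaching half of its carrying capacity \code{M} after \code{h}
#' years and saturating at \code{M}:
#' \code{N(t) = M (t-s)^2 / (h^2 + (t-s)^2)} for \code{t >= s}, else 0.
#'
#' @param t calendar time (vectorized).
#' @param M carrying capacity (\code{> 0}).
#' @param s start date of the expansion.
#' @param h half-time in years (\code{> 0}).
#' @return population size at \code{t}.
#' @export
logisticN <- function(t, M, s, h) {
  if (M <= 0 || h <= 0) stop("M and h must be positive")
  ifelse(t >= s, M * (t - s)^2 / (h^2 + (t - s)^2), 0)
}

#' Logistic trajectory as a function of time
#'
#' Convenience wrapper returning \code{function(t) logisticN(t, M, s, h)} with
#' the start date attached as attribute \code{"start"} (used by the simulators
#' as the hard lower time boundary of the component).
#'
#' @inheritParams logisticN
#' @return a vectorized function of calendar time.
#' @export
logisticTrajectory <- function(M, s, h) {
  f <- function(t) logisticN(t, M, s, h)
  attr(f, "start") <- s
  f
}

#' Simulate a dated tree under a time-varying coalescent
#'
#' Heterochronous coalescent with population size \code{N(t)}: with \code{k}
#' lineages the instantaneous coalescence rate at time \code{t} is
#' \code{k(k-1)/(2 N(t))}. Waiting times are drawn by time rescaling: the
#' cumulative rate is accumulated backwards in time (trapezoid steps, bisected
#' at the crossing) until it reaches a unit-exponential draw.
#'
#' @param dates tip sampling dates (named numeric vector).
#' @param Nfun vectorized positive function of calendar time (e.g. from
#'   [logisticTrajectory()]); an optional attribute \code{"start"} marks a
#'   date at which the population size hits zero, which no lineage may cross.
#' @param step integration step in years (default: span of the node dates
#'   divided by 1000).
#' @return a [datedTree()].
#' @export
simCoalescentNt <- function(dates, Nfun, step = NULL) {
  start <- attr(Nfun, "start")
  if (is.null(start)) start <- -Inf
  if (is.null(step)) step <- max(diff(range(dates)), 1) / 1000
  rate <- function(u, k) k * (k - 1) / (2 * pmax(Nfun(u), 1e-300))
  simCoalEngine(dates, function(t, k, tStop) {
    E <- stats::rexp(1)
    lower <- max(tStop, start + 1e-9)
    acc <- 0; cur <- t; rcur <- rate(cur, k)
    repeat {
      if (cur <= lower + 1e-12) {
        if (lower > tStop + 1e-12) return(lower)  # forced onto the component start
        return(NULL)                               # sampling event reached first
      }
      h <- min(step, cur - lower)
      nxt <- cur - h
      rnxt <- rate(nxt, k)
      seg <- (rcur + rnxt) / 2 * h
      if (acc + seg >= E) {
        f <- function(s) acc + (rcur + rate(s, k)) / 2 * (cur - s) - E
        return(stats::uniroot(f, c(nxt, cur), tol = 1e-10)$root)
      }
      acc <- acc + seg; cur <- nxt; rcur <- rnxt
    }
  })
}

#' Simulate a structured dated phylogeny
#'
#' Each population component genealogy is simulated independently under the
#' time-varying coalescent with its own trajectory and sampling scheme; the
#' component root lineages are then joined successively at the given
#' divergence dates (youngest join first; the oldest join is the root of the
#' combined tree).
#'
#' @param schemes list of tip sampling date vectors, one per component; tip
#'   labels are prefixed \code{c1_}, \code{c2_}, ... to stay unique.
#' @param trajectories list of population size functions (see
#'   [logisticTrajectory()]), one per component.
#' @param joinDates divergence dates, length \code{length(schemes) - 1},
#'   sorted decreasing (most recent first); each join must predate the
#'   component MRCAs it connects.
#' @return a [datedTree()].
#' @export
simStructured <- function(schemes, trajectories, joinDates) {
  ncomp <- length(schemes)
  if (ncomp < 2) stop("at least two components are required")
  if (length(trajectories) != ncomp) stop("one trajectory per component is required")
  if (length(joinDates) != ncomp - 1) stop("joinDates must have length ", ncomp - 1)
  if (any(diff(joinDates) > 0)) stop("joinDates must be sorted decreasing (youngest first)")
  comps <- vector("list", ncomp)
  rootDates <- numeric(ncomp)
  allDates <- numeric(0)
  for (j in seq_len(ncomp)) {
    sc <- schemes[[j]]
    if (is.null(names(sc))) names(sc) <- paste0("t", seq_along(sc))
    names(sc) <- paste0("c", j, "_", names(sc))
    D <- simCoalescentNt(sc, trajectories[[j]])
    comps[[j]] <- D
    rootDates[j] <- D$dates[length(sc) + 1]
    allDates <- c(allDates, sc)
  }
  sub <- vapply(comps, function(D) sub(";$", "", writeTree(D)), character(1))
  cur <- sub[1]; curRoot <- rootDates[1]
  for (j in 2:ncomp) {
    J <- joinDates[j - 1]
    if (J >= curRoot || J >= rootDates[j])
      stop("join date ", J, " is not older than the components it joins")
    cur <- sprintf("(%s:%.10f,%s:%.10f)", cur, curRoot - J, sub[j], rootDates[j] - J)
    curRoot <- J
  }
  phy <- readTree(text = paste0(cur, ";"))
  attachDates(phy, allDates, tol = 1e-4)
}

#' Add extra substitutions to selected terminal branches
#'
#' Emulates outlier tips (e.g. hypermutators or assembly artifacts) by adding
#' a fixed number of substitutions to the terminal branch of each selected
#' tip.
#'
#' @param L undated \code{phylo} (substitutions).
#' @param tips either tip labels, or a single count of tips to select at
#'   random.
#' @param extra substitutions to add to each selected terminal branch
#'   (\code{>= 0}).
#' @return the modified \code{phylo}, with the selected tip labels in
#'   attribute \code{"outliers"}.
#' @export
injectOutliers <- function(L, tips = 5, extra = 20) {
  if (extra < 0) stop("extra must be >= 0")
  if (is.numeric(tips) && length(tips) == 1) {
    tips <- sample(L$tip.label, tips)
  }
  bad <- setdiff(tips, L$tip.label)
  if (length(bad)) stop("unknown tips: ", paste(bad, collapse = ", "))
  idx <- match(match(tips, L$tip.label), L$edge[, 2])
  L$edge.length[idx] <- L$edge.length[idx] + extra
  attr(L, "outliers") <- tips
  L
}

#' Simulate a complete diagnostic test dataset
#'
#' One-stop simulator producing a dated coalescent tree and the undated
#' phylogeny obtained by applying a clock model to it, under one of the study
#' scenarios: \code{"constant"} (constant population size, strict clock),
#' \code{"relaxed"} (constant size, additive relaxed clock),
#' \code{"outliers"} (strict clock plus extra substitutions on a few terminal
#' branches) and \code{"structured"} (three single-year-sampled components
#' with logistic growth joined at older divergence dates, strict clock).
#'
#' @param scenario one of \code{"constant"}, \code{"relaxed"},
#'   \code{"outliers"}, \code{"structured"}.
#' @param n number of tips (split equally across components for
#'   \code{"structured"}).
#' @param tmin,tmax sampling date range (\code{"constant"}, \code{"relaxed"},
#'   \code{"outliers"}).
#' @param ne coalescent time scale in years.
#' @param mu clock rate (substitutions/year).
#' @param omega relaxation parameter (used by \code{"relaxed"}).
#' @param outliers,extra number of outlier tips and added substitutions
#'   (used by \code{"outliers"}).
#' @param sampleYears,rootDate,M,h structured-scenario layout: one sampling
#'   year per component, the date of the combined root, and the logistic
#'   carrying capacity and half-time shared by the components.
#' @return list with \code{dated} (a [datedTree()]), \code{undated} (phylo,
#'   substitutions), \code{dates} (tip dates), \code{model} (the generating
#'   [clockModel()]) and \code{truth} (generating parameter list).
#' @export
simulateDataset <- function(scenario = c("constant", "relaxed", "outliers", "structured"),
                            n = 100, tmin = 2010, tmax = 2020, ne = 1,
                            mu = 10, omega = 5, outliers = 5, extra = 20,
                            sampleYears = c(2000, 2010, 2020), rootDate = 1946,
                            M = 10, h = 5) {
  scenario <- match.arg(scenario)
  if (scenario == "structured") {
    ncomp <- length(sampleYears)
    per <- rep(floor(n / ncomp), ncomp); per[1] <- per[1] + n - sum(per)
    schemes <- lapply(seq_len(ncomp), function(j)
      stats::setNames(rep(sampleYears[j], per[j]), paste0("t", seq_len(per[j]))))
    traj <- lapply(sampleYears, function(y) logisticTrajectory(M, y - 30, h))
    joins <- seq(min(sampleYears) - 35, rootDate, length.out = ncomp - 1)
    D <- simStructured(schemes, traj, joinDates = joins)
    model <- clockModel("poisson", mu = mu)
    L <- applyClock(D, model)
    td <- stats::setNames(D$dates[seq_along(D$tree$tip.label)], D$tree$tip.label)
    return(list(dated = D, undated = L, dates = td, model = model,
                truth = list(scenario = scenario, mu = mu, rootDate = rootDate)))
  }
  td <- uniformDates(n, tmin, tmax)
  D <- simCoalescent(td, ne = ne)
  model <- switch(scenario,
                  relaxed = clockModel("negbin", mu = mu, omega = omega),
                  clockModel("poisson", mu = mu))
  L <- applyClock(D, model)
  truth <- list(scenario = scenario, mu = mu, ne = ne,
                rootDate = D$dates[n + 1])
  if (scenario == "relaxed") truth$omega <- omega
  if (scenario == "outliers") {
    L <- injectOutliers(L, tips = outliers, extra = extra)
    truth$outliers <- attr(L, "outliers")
  }
  list(dated = D, undated = L, dates = td, model = model, truth = truth)
}
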