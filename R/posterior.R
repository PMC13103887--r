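## Container for samples of (dated tree, mu, omega, Ne) from a dating MCMC or
## pseudo-posterior. All draws share the fixed input topology; only node dates
## and parameters vary, so dates are stored as a draws x nodes matrix.

newPosteriorSample <- function(tree, dates, mu, omega, ne, loglik, coalLoglik,
                               model, tipDates = NULL) {
  structure(list(tree = tree, dates = dates, mu = mu, omega = omega, ne = ne,
                 loglik = loglik, coalLoglik = coalLoglik, model = model,
                 tipDates = tipDates),
            class = "posteriorSample")
}

#' Number of draws in a posterior sample
#' @param ps a \code{posteriorSample}.
#' @return integer.
#' @export
nDraws <- function(ps) {
  stopifnot(inherits(ps, "posteriorSample"))
  nrow(ps$dates)
}

#' Extract one draw of a posterior sample
#'
#' @param ps a \code{posteriorSample}.
#' @param i draw index.
#' @return list with elements \code{tree} (a [datedTree()]), \code{mu},
#'   \code{omega}, \code{ne}.
#' @export
getDraw <- function(ps, i) {
  stopifnot(inherits(ps, "posteriorSample"))
  list(tree = datedTree(ps$tree, ps$dates[i, ]),
       mu = ps$mu[i], omega = ps$omega[i], ne = ps$ne[i])
}

#' Wrap a point estimate as a single-draw posterior sample
#'
#' Used to run posterior predictive checks on a maximum-likelihood or other
#' point-estimate dated tree: all replicate simulations then condition on this
#' single tree and parameter set.
#'
#' @param D a [datedTree()] point estimate.
#' @param mu clock rate estimate.
#' @param omega relaxation estimate (relaxed models only).
#' @param ne coalescent population size estimate (defaults to [mleAlpha()]).
#' @param model clock model family used for the inference.
#' @return a \code{posteriorSample} with one draw.
#' @export
asPosteriorSample <- function(D, mu, omega = NA, ne = NULL,
                              model = c("poisson", "gamma", "negbin", "argamma")) {
  stopifnot(inherits(D, "datedTree"))
  model <- match.arg(model)
  if (is.null(ne)) ne <- mleAlpha(D)
  newPosteriorSample(D$tree, matrix(D$dates, nrow = 1), mu, omega, ne,
                     loglik = NA_real_, coalLoglik = NA_real_, model = model)
}

#' @export
print.posteriorSample <- function(x, ...) {
  cat("Posterior sample of", nDraws(x), "dated trees (",
      length(x$tree$tip.label), "tips ), clock model:", x$model, "\n")
  cat("  mu:", format(stats::median(x$mu), digits = 4),
      "[", format(stats::quantile(x$mu, 0.025), digits = 4), ";",
      format(stats::quantile(x$mu, 0.975), digits = 4), "]\n")
  if (any(is.finite(x$omega)))
    cat("  omega:", format(stats::median(x$omega), digits = 4),
        "[", format(stats::quantile(x$omega, 0.025), digits = 4), ";",
        format(stats::quantile(x$omega, 0.975), digits = 4), "]\n")
  cat("  Ne:", format(stats::median(x$ne), digits = 4), "\n")
  n <- length(x$tree$tip.label)
  cat("  root date:", format(stats::median(x$dates[, n + 1]), digits = 7), "\n")
  invisible(x)
}

#' Write a posterior sample to multi-tree Newick and a CSV trace
#'
#' Writes \code{<prefix>.trees.nwk} (one dated tree per line, branch lengths
#' in years) and \code{<prefix>.trace.csv} with columns
#' \code{iteration,mu,omega,ne,loglik}.
#'
#' @param ps a \code{posteriorSample}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writePosterior <- function(ps, prefix) {
  stopifnot(inherits(ps, "posteriorSample"))
  treesFile <- paste0(prefix, ".trees.nwk")
  traceFile <- paste0(prefix, ".trace.csv")
  lines <- vapply(seq_len(nDraws(ps)),
                  function(i) writeTree(getDraw(ps, i)$tree), character(1))
  writeLines(lines, treesFile)
  utils::write.csv(data.frame(iteration = seq_len(nDraws(ps)), mu = ps$mu,
                              omega = ps$omega, ne = ps$ne, loglik = ps$loglik),
                   traceFile, row.names = FALSE)
  invisible(c(trees = treesFile, trace = traceFile))
}

#' Read a posterior sample from multi-tree Newick and a CSV trace
#'
#' @param treesFile multi-tree Newick file (dated trees, branch lengths in
#'   years, one per line).
#' @param traceFile CSV with columns \code{iteration,mu,omega,ne,loglik}.
#' @param dates tip dates (see [attachDates()]); \code{NULL} to parse from
#'   tip labels.
#' @param model clock model family the posterior was inferred under.
#' @return a \code{posteriorSample}.
#' @export
readPosterior <- function(treesFile, traceFile, dates = NULL,
                          model = c("poisson", "gamma", "negbin", "argamma")) {
  model <- match.arg(model)
  trees <- readTree(file = treesFile, multi = TRUE)
  trace <- utils::read.csv(traceFile)
  if (length(trees) != nrow(trace))
    stop("number of trees (", length(trees), ") and trace rows (", nrow(trace),
         ") differ")
  ref <- attachDates(trees[[1]], dates)
  datesMat <- t(vapply(trees, function(tr) {
    if (!identical(tr$tip.label, ref$tree$tip.label) ||
        !identical(tr$edge, ref$tree$edge))
      stop("all trees of a posterior sample must share the same topology and tip order")
    attachDates(tr, dates)$dates
  }, numeric(length(ref$dates))))
  newPosteriorSample(ref$tree, datesMat, trace$mu, trace$omega, trace$ne,
                     loglik = trace$loglik, coalLoglik = rep(NA_real_, nrow(trace)),
                     model = model)
}
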