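#' @importFrom ape read.tree write.tree is.rooted node.depth.edgelength Ntip Nnode
#' @importFrom stats setNames
NULL

## internal: number of tips / root node of a phylo
rootNode <- function(phy) length(phy$tip.label) + 1L

#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper around \code{ape::read.tree} that enforces the requirements of
#' the diagnostics: the tree must be rooted, every branch must have a length,
#' and no branch length may be negative.
#'
#' @param file path to a Newick file (one tree, or several for
#'   \code{multi = TRUE}).
#' @param text Newick string, used instead of \code{file} when given.
#' @param multi if \code{TRUE} return a list of trees (multi-tree Newick, one
#'   tree per line).
#' @return an object of class \code{phylo} (or a list of them). Branch length
#'   units (years or substitutions) are whatever the file encodes; the caller
#'   decides via [attachDates()] or by using the tree as an undated phylogeny.
#' @export
readTree <- function(file = NULL, text = NULL, multi = FALSE) {
  phy <- if (!is.null(text)) read.tree(text = text) else read.tree(file)
  if (is.null(phy)) stop("could not parse Newick input")
  if (inherits(phy, "multiPhylo")) {
    if (!multi) stop("input contains several trees; use multi = TRUE")
    return(lapply(unclass(phy), validateTree))
  }
  if (multi) return(list(validateTree(phy)))
  validateTree(phy)
}

validateTree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylogeny")
  if (is.null(phy$edge.length)) stop("branch lengths are required")
  if (anyNA(phy$edge.length)) stop("missing branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  if (!is.rooted(phy)) stop("tree must be rooted")
  phy
}

#' Write a phylogeny to Newick
#'
#' @param phy a \code{phylo} object or a [datedTree()] (in which case branch
#'   lengths are in years).
#' @param file output path; if \code{NULL} the Newick string is returned.
#' @param digits number of significant digits for branch lengths.
#' @export
writeTree <- function(phy, file = NULL, digits = 12) {
  if (inherits(phy, "datedTree")) phy <- phy$tree
  s <- write.tree(phy, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read tip sampling dates from CSV
#'
#' Expects a two-column CSV with header \code{tip,date}, dates as decimal
#' years.
#'
#' @param file path to the CSV file.
#' @return named numeric vector of dates.
#' @export
readTipDates <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("tip", "date") %in% names(d))) stop("dates CSV must have columns 'tip' and 'date'")
  setNames(as.numeric(d$date), as.character(d$tip))
}

#' Extract tip dates embedded in tip labels
#'
#' Dates may be carried as the suffix after the final \code{|} in each tip
#' label, e.g. \code{"isolate12|2014.37"}.
#'
#' @param phy a \code{phylo} object.
#' @return named numeric vector of dates (names are the full tip labels).
#' @export
tipDatesFromLabels <- function(phy) {
  lab <- phy$tip.label
  if (!all(grepl("|", lab, fixed = TRUE))) stop("not all tip labels carry a '|date' suffix")
  d <- as.numeric(sub(".*\\|", "", lab))
  if (anyNA(d)) stop("could not parse dates from tip labels")
  setNames(d, lab)
}

resolveTipDates <- function(phy, dates) {
  if (is.null(dates)) return(tipDatesFromLabels(phy))
  if (is.character(dates) && length(dates) == 1L) dates <- readTipDates(dates)
  if (is.data.frame(dates)) dates <- setNames(as.numeric(dates$date), as.character(dates$tip))
  if (is.null(names(dates))) {
    if (length(dates) != length(phy$tip.label)) stop("unnamed dates must match the number of tips")
    names(dates) <- phy$tip.label
  }
  miss <- setdiff(phy$tip.label, names(dates))
  if (length(miss)) stop("missing dates for tips: ", paste(miss, collapse = ", "))
  dates[phy$tip.label]
}

#' Construct a dated tree
#'
#' A dated tree couples a rooted topology with a calendar date (decimal years)
#' for every node. Branch durations are \code{date(child) - date(parent)} and
#' must be non-negative.
#'
#' @param phy rooted \code{phylo}; edge lengths, if present, are overwritten
#'   with the durations implied by \code{dates}.
#' @param dates numeric vector of node dates for all \code{Ntip + Nnode} nodes
#'   in ape node order (tips first).
#' @return object of class \code{datedTree}: a list with elements \code{tree}
#'   (phylo, branch lengths in years) and \code{dates}.
#' @export
datedTree <- function(phy, dates) {
  if (!inherits(phy, "phylo")) stop("phy must be a 'phylo' object")
  m <- length(phy$tip.label) + phy$Nnode
  if (length(dates) != m) stop("dates must have one entry per node (", m, ")")
  dur <- dates[phy$edge[, 2]] - dates[phy$edge[, 1]]
  if (any(dur < -1e-8)) stop("child dates must not precede parent dates")
  phy$edge.length <- pmax(dur, 0)
  structure(list(tree = phy, dates = unname(dates)), class = "datedTree")
}

#' Attach tip dates to a time-scaled tree
#'
#' Given a rooted tree whose branch lengths are in years and the sampling
#' dates of its tips, computes the implied date of every internal node and
#' checks that all tips give a consistent root date.
#'
#' @param phy rooted \code{phylo} with branch lengths in years.
#' @param dates tip dates: a named numeric vector, a \code{data.frame} with
#'   columns \code{tip} and \code{date}, a path to such a CSV, or \code{NULL}
#'   to parse dates from the tip labels (suffix after the last \code{|}).
#' @param tol tolerance (years) for consistency of the root date implied by
#'   different tips.
#' @return a [datedTree()].
#' @export
attachDates <- function(phy, dates = NULL, tol = 1e-6) {
  phy <- validateTree(phy)
  td <- resolveTipDates(phy, dates)
  n <- length(phy$tip.label)
  depth <- node.depth.edgelength(phy)
  root <- td - depth[seq_len(n)]
  if (diff(range(root)) > tol * max(1, diff(range(td)) + 1))
    stop("tip dates are inconsistent with the branch lengths (implied root dates differ by ",
         format(diff(range(root))), " years)")
  datedTree(phy, depth + root[1])
}

#' Branch durations of a dated tree
#'
#' @param D a [datedTree()].
#' @return numeric vector of durations in years, one per edge, in the order of
#'   \code{D$tree$edge}.
#' @export
branchDurations <- function(D) {
  stopifnot(inherits(D, "datedTree"))
  unname(D$dates[D$tree$edge[, 2]] - D$dates[D$tree$edge[, 1]])
}

#' @export
print.datedTree <- function(x, ...) {
  n <- length(x$tree$tip.label)
  cat("Dated phylogeny with", n, "tips\n")
  cat("  tip dates:", format(min(x$dates[seq_len(n)]), digits = 7), "to",
      format(max(x$dates[seq_len(n)]), digits = 7), "\n")
  cat("  root date:", format(x$dates[n + 1L], digits = 7), "\n")
  invisible(x)
}

## internal: canonical bipartition key of every edge.
## The key is the sorted set of tip labels on the side of the split NOT
## containing the reference tip (the alphabetically first label), so that keys
## are invariant to child order, tip numbering, and to which side is listed.
edgeSplitKeys <- function(phy) {
  n <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  phy2 <- ape::reorder.phylo(phy, "postorder")
  m <- n + phy$Nnode
  below <- vector("list", m)
  for (i in seq_len(n)) below[[i]] <- phy$tip.label[i]
  for (j in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[j, 1]; ch <- phy2$edge[j, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(nrow(phy$edge))
  for (j in seq_len(nrow(phy$edge))) {
    s <- below[[phy$edge[j, 2]]]
    if (ref %in% s) s <- setdiff(phy$tip.label, s)
    keys[j] <- paste(sort(s), collapse = "\r")
  }
  keys
}

#' Match branches between a dated and an undated phylogeny
#'
#' Every branch of the dated tree \code{D} is matched to the branch of the
#' undated tree \code{L} that separates the leaves in the same way. The two
#' branches adjacent to the root of \code{D} define the same leaf bipartition,
#' which corresponds to a single (unrooted) branch \code{x} of \code{L}; its
#' substitutions are later split between the two root branches in proportion
#' to their durations (see [splitRootSubstitutions()]).
#'
#' @param D a [datedTree()] or a rooted \code{phylo} giving the dated topology.
#' @param L a rooted \code{phylo} with branch lengths in substitutions.
#' @return object of class \code{branchMatch}: list with \code{l} (substitutions
#'   per edge of \code{D}, \code{NA} for the two root-adjacent edges),
#'   \code{rootEdges} (indices of those two edges, or \code{NULL} when the root
#'   of \code{D} is a polytomy), and \code{lx} (substitutions on the shared
#'   root branch of \code{L}).
#' @export
matchBranches <- function(D, L) {
  phyD <- if (inherits(D, "datedTree")) D$tree else D
  if (!setequal(phyD$tip.label, L$tip.label))
    stop("the dated and undated trees have different leaf sets")
  if (any(L$edge.length < 0)) stop("negative substitution branch lengths")
  keyD <- edgeSplitKeys(phyD)
  keyL <- edgeSplitKeys(L)
  lmap <- tapply(L$edge.length, keyL, sum)  # the two root edges of L share a key
  rootEdges <- which(phyD$edge[, 1] == rootNode(phyD))
  l <- as.numeric(lmap[keyD])
  if (anyNA(l)) {
    bad <- unique(keyD[is.na(l)])
    stop("topology mismatch: ", length(bad), " bipartition(s) of the dated tree absent ",
         "from the undated tree: ", paste(gsub("\r", "|", bad), collapse = "; "))
  }
  out <- list(l = l, rootEdges = NULL, lx = NULL)
  if (length(rootEdges) == 2L) {
    out$rootEdges <- rootEdges
    out$lx <- unname(l[rootEdges[1]])
    out$l[rootEdges] <- NA_real_
  }
  structure(out, class = "branchMatch")
}

#' Split the substitutions of the root branch
#'
#' The single undated branch at the root split carries \code{lx} substitutions;
#' they are divided between the two root-adjacent dated branches in proportion
#' to their durations: \code{la = lx*da/(da+db)}, \code{lb = lx*db/(da+db)}.
#' When both durations are zero the split is 50/50.
#'
#' @param lx substitutions on the shared branch (\code{>= 0}).
#' @param da,db durations in years of the two root-adjacent branches.
#' @return numeric vector \code{c(la, lb)}; always sums to \code{lx}.
#' @export
splitRootSubstitutions <- function(lx, da, db) {
  if (lx < 0 || da < 0 || db < 0) stop("negative inputs to root split")
  if (da + db == 0) return(c(lx / 2, lx / 2))
  c(lx * da / (da + db), lx * db / (da + db))
}

## internal: per-edge substitution values for the edges of D, with the root
## pair filled in from the proportional split given current durations.
effectiveSubstitutions <- function(match, durations) {
  l <- match$l
  if (!is.null(match$rootEdges)) {
    re <- match$rootEdges
    l[re] <- splitRootSubstitutions(match$lx, durations[re[1]], durations[re[2]])
  }
  l
}

## internal: trivial branch match for the common case where the dated tree is
## built on the topology of L itself (as in the MCMC dating engine).
selfMatch <- function(L) {
  rootEdges <- which(L$edge[, 1] == rootNode(L))
  l <- L$edge.length
  out <- list(l = l, rootEdges = NULL, lx = NULL)
  if (length(rootEdges) == 2L) {
    out$rootEdges <- rootEdges
    out$lx <- sum(l[rootEdges])
    out$l[rootEdges] <- NA_real_
  }
  structure(out, class = "branchMatch")
}

#' Summary statistics of a phylogeny's branch lengths
#'
#' Computes the four summaries used by the posterior predictive check: mean,
#' sample variance and maximum of the branch lengths, and the tree stemminess
#' (sum of internal branch lengths divided by the total branch length; both
#' root-adjacent branches count as internal when they lead to internal nodes).
#'
#' @param phy a \code{phylo} or [datedTree()].
#' @return named numeric vector with elements \code{mean}, \code{variance},
#'   \code{max}, \code{stemminess}.
#' @export
treeSummaryStats <- function(phy) {
  if (inherits(phy, "datedTree")) phy <- phy$tree
  e <- phy$edge.length
  if (length(e) < 2) stop("at least two branches are required")
  tot <- sum(e)
  if (tot == 0) stop("stemminess undefined: total branch length is zero")
  internal <- phy$edge[, 2] > length(phy$tip.label)
  c(mean = mean(e), variance = stats::var(e), max = max(e),
    stemminess = sum(e[internal]) / tot)
}
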