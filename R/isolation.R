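# One-dimensional isolation forest for per-bin read-depth anomaly scoring.
#
# Each tree is grown on a random subsample of bins by recursive random
# splits on the RD value; a bin that is isolated after few splits (a short
# path) has an RD far from the bulk, in either direction.  Because the
# feature is one-dimensional, a fitted tree is just a partition of the
# real line into intervals, so each tree is flattened to sorted
# breakpoints plus a per-interval path length, and scoring a profile is a
# findInterval() lookup per tree.

.harmonic <- function(n) log(n) + 0.5772156649015329

# expected path length of an unsuccessful BST search among n points;
# the standard normalizer c(n)
.cFactor <- function(n) {
  ifelse(n <= 1, 0, 2 * .harmonic(n - 1) - 2 * (n - 1) / n)
}

# grow one tree; returns the nested node structure plus a flattened form
# (sorted interior breakpoints + path length per interval) used for fast
# scoring: a 1-D tree is just a partition of the real line
.growTree <- function(values, depthLimit) {
  breaks <- numeric(0)
  path <- list()
  recurse <- function(v, depth) {
    lo <- min(v); hi <- max(v)
    if (length(v) <= 1L || depth >= depthLimit || lo == hi) {
      # leaf: interval inherits depth plus the average extra path through
      # an unsplit node of this size
      path[[length(path) + 1L]] <<- depth + .cFactor(length(v))
      return(list(leaf = TRUE, size = length(v)))
    }
    split <- stats::runif(1, lo, hi)
    breaks <<- c(breaks, split)
    left <- recurse(v[v < split], depth + 1)   # left first, in-order leaves
    right <- recurse(v[v >= split], depth + 1)
    list(leaf = FALSE, split = split, left = left, right = right)
  }
  root <- recurse(values, 0)
  # leaves were emitted in left-to-right (in-order) sequence, so the sorted
  # breakpoints delimit the path lengths in the same order
  list(breaks = sort(breaks), pathlen = unlist(path), root = root)
}

#' Build a 1-D isolation forest over per-bin read depths
#'
#' Grows `nTrees` isolation trees, each on `subsample` bins drawn without
#' replacement from `rdValues`, splitting on the RD value at a uniformly
#' random point between the node's min and max.  Tree depth is capped at
#' `ceiling(log2(subsample))`; capped leaves contribute the usual
#' average-path adjustment for their size.  Defaults follow the detector's
#' standard configuration of 256 trees over 256 bins each.
#'
#' @param rdValues Numeric vector of per-bin read depths (unmasked bins).
#' @param nTrees Number of trees (default 256).
#' @param subsample Bins per tree (default 256); reduced to
#'   `length(rdValues)` with a warning when the profile is smaller.
#' @param seed Integer seed making the forest deterministic; `NULL` uses
#'   the current RNG state.
#' @return An object of class `isolationForest` (a list of flattened
#'   trees), for use with [anomalyScores()].
#' @export
buildIsolationForest <- function(rdValues, nTrees = 256L, subsample = 256L,
                                 seed = NULL) {
  stopifnot(is.numeric(rdValues), length(rdValues) >= 1L,
            nTrees >= 1L, subsample >= 2L)
  if (any(!is.finite(rdValues)))
    stop("rdValues must be finite")
  if (length(rdValues) < subsample) {
    warning("fewer bins (", length(rdValues), ") than subsample (",
            subsample, "); reducing subsample")
    subsample <- length(rdValues)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  depthLimit <- ceiling(log2(subsample))
  trees <- vector("list", nTrees)
  samples <- vector("list", nTrees)
  for (t in seq_len(nTrees)) {
    idx <- sample.int(length(rdValues), subsample)
    samples[[t]] <- idx
    trees[[t]] <- .growTree(rdValues[idx], depthLimit)
  }
  structure(list(trees = trees, samples = samples, subsample = subsample,
                 nTrees = nTrees),
            class = "isolationForest")
}

#' Raw anomaly scores from an isolation forest
#'
#' The standard isolation-forest score `s = 2^(-E[h] / c(subsample))`,
#' where `E[h]` is the mean path length of the query value across trees
#' and `c()` the average-path normalizer.  Scores lie in (0,1); values far
#' from the bulk of the RD distribution (losses and gains alike) isolate
#' quickly and score high.
#'
#' @param forest An `isolationForest` from [buildIsolationForest()].
#' @param rdValues Numeric vector of per-bin read depths to score.
#' @return Numeric vector of scores, one per element of `rdValues`.
#' @export
anomalyScores <- function(forest, rdValues) {
  stopifnot(inherits(forest, "isolationForest"), is.numeric(rdValues))
  h <- numeric(length(rdValues))
  for (tr in forest$trees) {
    iv <- findInterval(rdValues, tr$breaks) + 1L
    h <- h + tr$pathlen[iv]
  }
  h <- h / forest$nTrees
  2^(-h / .cFactor(forest$subsample))
}
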