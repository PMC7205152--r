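# Tumor purity inference from loss-region read depths.
#
# In an admixed sample with tumor fraction alpha, a region carrying c
# tumor copies has expected RD  r_bar * (alpha*c + 2*(1-alpha)) / 2, with
# r_bar the RD of the copy-number-neutral diploid state.  Losses take only
# two states (c = 1 heterozygous, c = 0 homozygous), so given a candidate
# alpha the observed loss RDs can be (i) deconvolved into pure-tumor
# "absolute" RDs, (ii) split into the two states by 1-D two-means, and
# (iii) compared to their model expectations.  The alpha minimizing the
# mean absolute mismatch over an exhaustive grid is the purity estimate.

#' Construct a LossSet
#'
#' @param x Either a `GRanges` of CNV regions with metadata columns
#'   `direction` and `observed_rd` (only `direction == "loss"` rows are
#'   kept), or a bare numeric vector of observed loss-region RDs.
#' @return A [LossSet-class].
#' @examples
#' lossSet(c(5, 7.5))
#' @export
lossSet <- function(x) {
  if (is(x, "GRanges")) {
    if (is.null(mcols(x)$direction) || is.null(mcols(x)$observed_rd))
      stop("GRanges input needs 'direction' and 'observed_rd' columns")
    keep <- mcols(x)$direction == "loss"
    new("LossSet", regions = x[keep], R = mcols(x)$observed_rd[keep])
  } else if (is.numeric(x)) {
    if (any(!is.finite(x)) || any(x < 0))
      stop("observed RDs must be finite and non-negative")
    new("LossSet", regions = GRanges(), R = as.numeric(x))
  } else stop("x must be a GRanges of CNV calls or a numeric RD vector")
}

#' Recover absolute (pure-tumor) read depths
#'
#' Removes the normal-cell contribution from observed RDs at a candidate
#' purity: `Q = (R - (1 - alpha) * rBar) / alpha`.  Negative values are
#' permitted here — they arise when the candidate purity understates the
#' normal contamination and are informative for the downstream two-group
#' split.
#'
#' @param R Numeric vector of observed RDs.
#' @param alpha Candidate tumor purity in (0, 1].
#' @param rBar Genome-wide mean RD (> 0).
#' @return Numeric vector `Q`, same length as `R`.
#' @examples
#' recoverAbsoluteRD(c(5, 7.5), alpha = 0.5, rBar = 10)  # 0 5
#' @export
recoverAbsoluteRD <- function(R, alpha, rBar) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  if (!is.numeric(rBar) || length(rBar) != 1L || rBar <= 0)
    stop("rBar must be a single positive value")
  (R - (1 - alpha) * rBar) / alpha
}

# exact 1-D two-means via threshold scan over sorted breakpoints;
# returns integer 0/1 labels (0 = lower-mean cluster)
.classify1d <- function(Q, warn = TRUE) {
  n <- length(Q)
  if (n < 2L) stop("need >= 2 loss regions to classify")
  if (max(Q) == min(Q)) {
    if (warn) warning("all absolute RDs identical: no separation, ",
                      "labelling all regions heterozygous")
    return(rep(1L, n))
  }
  o <- order(Q)
  qs <- Q[o]
  cs <- cumsum(qs)
  cs2 <- cumsum(qs^2)
  t <- seq_len(n - 1L)
  # within-cluster sum of squares of {1..t} and {t+1..n}
  wcss <- (cs2[t] - cs[t]^2 / t) +
          (cs2[n] - cs2[t] - (cs[n] - cs[t])^2 / (n - t))
  tbest <- which.min(wcss)
  labels <- integer(n)
  labels[o] <- rep(c(0L, 1L), c(tbest, n - tbest))
  labels
}

#' Classify losses into homozygous and heterozygous
#'
#' Splits the recovered absolute RDs into two groups by exact
#' one-dimensional two-means clustering: the globally optimal threshold is
#' found by scanning all sorted-breakpoint partitions, which provably
#' attains the within-cluster sum-of-squares optimum that Lloyd-style
#' K-means (K = 2) converges toward, with no dependence on a random
#' initialization.  The lower-mean group is labelled 0 (homozygous loss,
#' both copies gone), the higher 1 (heterozygous loss, one copy left).
#'
#' @param Q Numeric vector of absolute RDs (length >= 2).
#' @return Integer 0/1 vector aligned with `Q`.
#' @examples
#' classifyLosses(c(0, 5))            # 0 1
#' classifyLosses(c(0.1, 0, 5.2, 4.9, 5.0))
#' @export
classifyLosses <- function(Q) {
  if (!is.numeric(Q) || any(!is.finite(Q)))
    stop("Q must be finite numeric")
  .classify1d(Q, warn = TRUE)
}

#' Model-expected read depths of loss regions
#'
#' `E = alpha * rBar * B / 2 + (1 - alpha) * rBar`: a heterozygous loss
#' (B = 1) keeps one tumor copy contributing `alpha * rBar / 2`, a
#' homozygous loss (B = 0) contributes nothing from the tumor fraction,
#' and the normal fraction always contributes `(1 - alpha) * rBar`.
#'
#' @param B Integer/numeric 0/1 labels.
#' @param alpha Candidate purity in (0, 1].
#' @param rBar Genome-wide mean RD.
#' @return Numeric vector of expected RDs.
#' @examples
#' expectedRD(c(0, 1), alpha = 0.5, rBar = 10)  # 5 7.5
#' @export
expectedRD <- function(B, alpha, rBar) {
  if (!all(B %in% c(0, 1))) stop("B must contain only 0s and 1s")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  alpha * rBar * B / 2 + (1 - alpha) * rBar
}

#' Deviation between expected and observed loss RDs
#'
#' The grid search's objective: the mean absolute difference between
#' model-expected and observed RDs over the n loss regions.
#'
#' @param E,R Numeric vectors of equal length (>= 1).
#' @return A single non-negative number.
#' @examples
#' lossDeviation(c(6, 8), c(5, 7.5))  # 0.75
#' @export
lossDeviation <- function(E, R) {
  if (length(E) != length(R))
    stop("E and R must have equal length")
  if (length(E) == 0L) stop("need >= 1 loss region")
  mean(abs(E - R))
}

#' Estimate tumor purity by exhaustive grid search
#'
#' For every candidate purity alpha on the grid, the observed loss-region
#' RDs are deconvolved to absolute RDs ([recoverAbsoluteRD()]), split into
#' homozygous/heterozygous groups ([classifyLosses()]), mapped to their
#' model expectations ([expectedRD()]) and scored by the mean absolute
#' deviation ([lossDeviation()]).  The smallest alpha attaining the
#' minimum deviation is returned (the tie-break makes the search
#' deterministic).  When a candidate alpha collapses all absolute RDs onto
#' one value the no-separation rule labels every region heterozygous and
#' the candidate is still scored, so hom-only or het-only genomes are
#' handled by the deviation curve itself.
#'
#' @param losses A [LossSet-class], a `GRanges` of CNV calls, or a numeric
#'   vector of observed loss RDs (needs >= 2 regions).
#' @param rBar Genome-wide mean RD.
#' @param alphaMin,alphaMax,step Grid specification; defaults 0.05, 0.95,
#'   0.01.
#' @return A [PurityEstimate-class].
#' @examples
#' est <- gridSearchPurity(c(5, 7.5), rBar = 10)
#' alphaHat(est)  # 0.5
#' @export
gridSearchPurity <- function(losses, rBar, alphaMin = 0.05, alphaMax = 0.95,
                             step = 0.01) {
  if (!is(losses, "LossSet")) losses <- lossSet(losses)
  R <- losses@R
  if (length(R) < 2L)
    stop("need >= 2 loss regions for purity estimation (got ",
         length(R), ")")
  if (!is.numeric(rBar) || length(rBar) != 1L || rBar <= 0)
    stop("rBar must be a single positive value")
  if (any(R >= rBar))
    warning(sum(R >= rBar), " loss region(s) have observed RD >= rBar")
  if (!(alphaMin > 0 && alphaMin <= alphaMax && alphaMax < 1))
    stop("need 0 < alphaMin <= alphaMax < 1")
  if (step <= 0) stop("step must be positive")
  grid <- seq(alphaMin, alphaMax, by = step)
  grid <- round(grid, 10)
  if (length(grid) == 0L) stop("empty purity grid")
  devs <- vapply(grid, function(a) {
    Q <- recoverAbsoluteRD(R, a, rBar)
    B <- .classify1d(Q, warn = FALSE)
    lossDeviation(expectedRD(B, a, rBar), R)
  }, numeric(1))
  iHat <- which.min(devs)          # first minimum = smallest alpha
  aHat <- grid[iHat]
  BHat <- .classify1d(recoverAbsoluteRD(R, aHat, rBar), warn = FALSE)
  new("PurityEstimate", alphaGrid = grid, deviations = devs,
      alphaHat = aHat, dMin = devs[iHat], BHat = BHat, R = R, rBar = rBar)
}

#' Write the purity report
#'
#' A TSV of the full deviation curve (columns `alpha`, `deviation`),
#' preceded by comment lines summarising the solution
#' (`# alpha_hat=`, `# d_min=`, `# n_losses=`, `# n_hom=`, `# n_het=`).
#'
#' @param estimate A [PurityEstimate-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePurityReport <- function(estimate, path) {
  stopifnot(is(estimate, "PurityEstimate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# alpha_hat=%.2f", estimate@alphaHat),
    sprintf("# d_min=%.8g", estimate@dMin),
    sprintf("# n_losses=%d", length(estimate@BHat)),
    sprintf("# n_hom=%d", sum(estimate@BHat == 0L)),
    sprintf("# n_het=%d", sum(estimate@BHat == 1L))), con)
  utils::write.table(deviations(estimate), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
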