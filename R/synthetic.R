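# Synthetic admixed tumor-normal RD profiles with known purity and
# planted integer copy numbers.  Simulation happens at the binned-RD
# level: per-bin counts are drawn around the mixture mean
#   baseRD * (purity * cn + 2 * (1 - purity)) / 2,
# which is exactly the quantity the purity and copy-number models consume,
# so every downstream stage is testable without read-level simulation.

#' Default planted-segment layout
#'
#' 25 non-overlapping segments: 10 losses (five at copy number 0, five at
#' 1 — guaranteeing both loss states exist, which purity inference
#' requires) and 15 gains (five each at 4, 5 and 8).  Segment lengths are
#' drawn uniformly from 20--100 bins and each segment is placed inside its
#' own equal-width block of the genome, so segments never overlap and are
#' separated by normal-copy stretches.
#'
#' @param nBins Genome length in bins.
#' @param seed Optional integer seed for lengths/offsets/CN shuffling.
#' @return A `data.frame` with columns `startBin`, `endBin` (0-based
#'   half-open, in bins) and `cn`.
#' @export
defaultSegments <- function(nBins = 40000L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  cns <- c(rep(0L, 5), rep(1L, 5), rep(4L, 5), rep(5L, 5), rep(8L, 5))
  k <- length(cns)
  block <- nBins %/% k
  if (block < 110L)
    stop("nBins too small for the default layout (need >= ", 110L * k, ")")
  cns <- sample(cns)
  len <- sample(20:100, k, replace = TRUE)
  off <- vapply(len, function(l) sample.int(block - l - 5L, 1L), integer(1))
  start <- (seq_len(k) - 1L) * block + off
  data.frame(startBin = start, endBin = start + len, cn = cns)
}

.validSegments <- function(segments, nBins) {
  stopifnot(is.data.frame(segments),
            all(c("startBin", "endBin", "cn") %in% names(segments)))
  if (nrow(segments) == 0L) return(segments)
  if (any(segments$startBin < 0 | segments$endBin > nBins |
          segments$startBin >= segments$endBin))
    stop("segments must satisfy 0 <= startBin < endBin <= nBins")
  if (any(segments$cn < 0) || any(segments$cn != round(segments$cn)))
    stop("segment cn must be a non-negative integer")
  o <- order(segments$startBin)
  s <- segments[o, ]
  if (nrow(s) > 1L && any(s$startBin[-1] < s$endBin[-nrow(s)]))
    stop("segments must not overlap")
  s
}

#' Simulation configuration
#'
#' Captures everything needed to generate one admixed profile.  Defaults
#' emulate a 10x-coverage single-chromosome study: 40,000 bins of 1 kb
#' (about one chromosome-21 length), base RD 100 (100 bp reads at 10x give
#' about 100 read starts per 1 kb bin), Poisson count noise, and the
#' [defaultSegments()] layout of planted copy numbers {0, 1, 4, 5, 8}.
#'
#' @param purity True tumor purity, strictly inside (0, 1).
#' @param nBins,binSize,baseRD Genome size in bins, bin width in bp, and
#'   mean RD of a copy-number-neutral bin.
#' @param segments Planted segments as from [defaultSegments()]; `NULL`
#'   draws the default layout (using `seed`).
#' @param noise `"poisson"` (default), `"nbinom"` (over-dispersed, see
#'   `dispersion`) or `"none"` (bins carry their exact means).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); used only when `noise = "nbinom"`.
#' @param gcBiasAmplitude Amplitude of an optional smooth multiplicative
#'   GC bias (0 disables; 0.1 modulates means by +-10%).
#' @param seed Integer seed; fixes layout and noise, making the profile
#'   reproducible bit-for-bit.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(purity, nBins = 40000L, binSize = 1000L, baseRD = 100,
                      segments = NULL, noise = c("poisson", "nbinom", "none"),
                      dispersion = 0.1, gcBiasAmplitude = 0, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.numeric(purity) || length(purity) != 1L ||
      purity <= 0 || purity >= 1)
    stop("purity must lie strictly inside (0, 1)")
  stopifnot(nBins >= 2L, binSize >= 1L, baseRD > 0, dispersion >= 0,
            gcBiasAmplitude >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(segments)) segments <- defaultSegments(nBins)
  segments <- .validSegments(segments, nBins)
  structure(list(purity = purity, nBins = as.integer(nBins),
                 binSize = as.integer(binSize), baseRD = baseRD,
                 segments = segments, noise = noise,
                 dispersion = dispersion,
                 gcBiasAmplitude = gcBiasAmplitude, seed = seed),
            class = "simConfig")
}

#' Simulate an admixed tumor-normal read-depth profile
#'
#' Per-bin expected RD follows the mixture identity
#' `baseRD * (purity * cn + 2 * (1 - purity)) / 2` (cn = 2 outside planted
#' segments); counts are then drawn from the configured noise law.  A
#' smooth sinusoidal GC covariate is always attached to the bins; when
#' `gcBiasAmplitude > 0` the means are additionally modulated along it, so
#' [correctGCBias()] can be exercised against a known bias.
#'
#' @param config A `simConfig` (or a bare purity value, which is passed to
#'   [simConfig()] with all defaults).
#' @return A list with `profile` (an [RDProfile-class] on contig
#'   `"simchr"`) and `truth` (a [SimTruth-class]).
#' @examples
#' sim <- simulateProfile(simConfig(0.5, nBins = 2000, seed = 1))
#' meanRD(sim$profile)
#' @export
simulateProfile <- function(config) {
  if (is.numeric(config)) config <- simConfig(config)
  stopifnot(inherits(config, "simConfig"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  n <- config$nBins
  cn <- rep(2L, n)
  seg <- config$segments
  for (i in seq_len(nrow(seg)))
    cn[(seg$startBin[i] + 1L):seg$endBin[i]] <- seg$cn[i]
  mu <- config$baseRD * (config$purity * cn + 2 * (1 - config$purity)) / 2

  phase <- 2 * pi * seq_len(n) / 2000
  gc <- 0.45 + 0.08 * sin(phase)
  muBiased <- if (config$gcBiasAmplitude > 0)
    mu * (1 + config$gcBiasAmplitude * sin(phase)) else mu

  rd <- switch(config$noise,
    poisson = as.numeric(rpois(n, muBiased)),
    nbinom = if (config$dispersion == 0)
               as.numeric(rpois(n, muBiased))
             else
               as.numeric(rnbinom(n, mu = muBiased,
                                  size = 1 / config$dispersion)),
    none = muBiased)

  gr <- .tileContig("simchr", n * config$binSize, config$binSize)
  mcols(gr)$gc <- gc
  mcols(gr)$n_frac <- rep(0, n)
  mcols(gr)$rd_raw <- rd
  mcols(gr)$rd <- rd
  mcols(gr)$masked <- rep(FALSE, n)
  profile <- .newRDProfile(gr, config$binSize)

  segGR <- GRanges(rep("simchr", nrow(seg)),
                   IRanges(start = seg$startBin * config$binSize + 1L,
                           end = seg$endBin * config$binSize))
  mcols(segGR)$cn <- as.integer(seg$cn)
  truth <- new("SimTruth", purity = config$purity, segments = segGR,
               expectedRD = mu, baseRD = config$baseRD)
  list(profile = profile, truth = truth)
}

#' Score a purity / copy-number estimate against simulation truth
#'
#' @param estimate A [PurityEstimate-class].
#' @param cnCalls A `GRanges` from [absoluteCopyNumber()] (may be empty).
#' @param truth The [SimTruth-class] of the same profile.
#' @return A list: `purityError` = |alphaHat - true purity|; `cnAccuracy`
#'   = fraction of planted segments whose best >= 50%-reciprocal-overlap
#'   call carries the true integer copy number (unmatched segments count
#'   as wrong); `nMatched`, `nSegments`.
#' @export
evaluateEstimate <- function(estimate, cnCalls, truth) {
  stopifnot(is(estimate, "PurityEstimate"), is(truth, "SimTruth"))
  segs <- truth@segments
  res <- list(purityError = abs(estimate@alphaHat - truth@purity),
              nSegments = length(segs))
  correct <- 0L; matched <- 0L
  if (length(segs) && length(cnCalls)) {
    hits <- findOverlaps(segs, cnCalls)
    ov <- width(pintersect(segs[queryHits(hits)], cnCalls[subjectHits(hits)]))
    recip <- ov >= 0.5 * width(segs)[queryHits(hits)] &
             ov >= 0.5 * width(cnCalls)[subjectHits(hits)]
    for (i in seq_along(segs)) {
      sel <- which(queryHits(hits) == i & recip)
      if (length(sel) == 0L) next
      matched <- matched + 1L
      best <- sel[which.max(ov[sel])]
      if (mcols(cnCalls)$cn_int[subjectHits(hits)[best]] ==
          mcols(segs)$cn[i])
        correct <- correct + 1L
    }
  }
  res$nMatched <- matched
  res$cnAccuracy <- if (length(segs)) correct / length(segs) else NA_real_
  res
}
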