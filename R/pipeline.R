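#' Run the full purity / copy-number pipeline
#'
#' Chains the stages: binned RD profiling (or loading a ready profile),
#' CNV detection (or importing external calls), purity grid search over
#' the loss regions, and absolute copy-number conversion of all regions.
#' Every stage can also be run on its own; the file-based handoff uses the
#' TSV/BED formats of [writeRDProfile()], [writeCNVCalls()],
#' [writePurityReport()] and [writeCNReport()], so any external CNV caller
#' can replace the detection stage.
#'
#' @param bam,reference BAM + FASTA input for profiling; ignored when
#'   `profile` is given.
#' @param profile An [RDProfile-class], or the path of a profile TSV.
#' @param cnv Optional `GRanges` of CNV calls or path of a BED file; when
#'   `NULL` the built-in detector runs.
#' @param binSize,nFracThreshold Profiling parameters (1000 bp, 0.5).
#' @param level,nTrees,subsample,lam Detection parameters (see
#'   [detectCNV()]).
#' @param alphaMin,alphaMax,alphaStep Purity grid (0.05, 0.95, 0.01).
#' @param excludeCNVFromRBar When `TRUE`, the mean RD is recomputed over
#'   bins outside the called CNV regions before purity inference; the
#'   default `FALSE` keeps the plain genome-wide mean (CNVs occupy a small
#'   fraction of the genome).
#' @param seed Integer seed for the detector.
#' @param outDir Optional directory; when given, all reports are written
#'   (`profile.tsv`, `calls.bed`, `calls.tsv`, `purity.tsv`,
#'   `cn_report.tsv`).
#' @return A list with `profile`, `rBar`, `regions`, `estimate`
#'   (a [PurityEstimate-class]) and `calls` (regions with `cn_real` /
#'   `cn_int`).
#' @export
runPipeline <- function(bam = NULL, reference = NULL, profile = NULL,
                        cnv = NULL, binSize = 1000L, nFracThreshold = 0.5,
                        level = 0.01, nTrees = 256L, subsample = 256L,
                        lam = NULL, alphaMin = 0.05, alphaMax = 0.95,
                        alphaStep = 0.01, excludeCNVFromRBar = FALSE,
                        seed = NULL, outDir = NULL) {
  if (is.null(profile)) {
    if (is.null(bam) || is.null(reference))
      stop("provide either a profile or bam + reference")
    profile <- binReadCounts(bam, reference, binSize = binSize)
    profile <- maskNBins(profile, nFracThreshold = nFracThreshold)
    profile <- correctGCBias(profile)
  } else if (is.character(profile)) {
    profile <- readRDProfile(profile)
  }
  stopifnot(is(profile, "RDProfile"))
  rBar <- meanRD(profile)

  if (is.null(cnv)) {
    det <- detectCNV(profile, level = level, nTrees = nTrees,
                     subsample = subsample, lam = lam, seed = seed)
    regions <- det$regions
  } else if (is.character(cnv)) {
    regions <- loadExternalCalls(cnv, profile, rBar = rBar)
  } else {
    regions <- cnv
  }

  if (excludeCNVFromRBar && length(regions)) {
    b <- profile@bins[!mcols(profile@bins)$masked]
    out <- GenomicRanges::countOverlaps(b, regions) == 0L
    if (any(out)) rBar <- mean(mcols(b)$rd[out])
    # regions keep their observed RDs; only the reference level moves
  }

  losses <- lossSet(regions)
  if (length(losses) < 2L)
    stop(structure(class = c("puracnTooFewLosses", "error", "condition"),
                   list(message = paste0(
                     "purity estimation needs >= 2 loss regions; got ",
                     length(losses)), call = NULL)))
  estimate <- gridSearchPurity(losses, rBar, alphaMin = alphaMin,
                               alphaMax = alphaMax, step = alphaStep)
  calls <- absoluteCopyNumber(regions, alpha = estimate@alphaHat,
                              rBar = rBar)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRDProfile(profile, file.path(outDir, "profile.tsv"))
    writeCNVCalls(calls, bedPath = file.path(outDir, "calls.bed"),
                  tsvPath = file.path(outDir, "calls.tsv"))
    writePurityReport(estimate, file.path(outDir, "purity.tsv"))
    writeCNReport(calls, file.path(outDir, "cn_report.tsv"),
                  estimate = estimate)
  }
  list(profile = profile, rBar = rBar, regions = regions,
       estimate = estimate, calls = calls)
}

#' Replicated purity-recovery study on synthetic profiles
#'
#' For each purity level, simulates `nReps` admixed profiles with planted
#' copy numbers ([simConfig()] defaults), runs the full detector + purity
#' + copy-number pipeline, and scores each replicate against the
#' simulation truth with [evaluateEstimate()].
#'
#' @param purities Numeric vector of true purities (default 0.2--0.8 by
#'   0.1).
#' @param nReps Replicates per purity level.
#' @param seed Integer master seed; per-replicate seeds are derived from
#'   it so the whole study is reproducible.
#' @param nBins,baseRD Profile size and neutral-state RD.
#' @param level Detection significance level.
#' @return A `data.frame` with one row per replicate: `purity`, `rep`,
#'   `alphaHat`, `purityError`, `cnAccuracy`, `nMatched`, `nSegments`,
#'   `nLosses`.
#' @export
runRecoveryStudy <- function(purities = seq(0.2, 0.8, by = 0.1), nReps = 10L,
                             seed = 1L, nBins = 40000L, baseRD = 100,
                             level = 0.01) {
  rows <- list()
  for (pi in seq_along(purities)) {
    for (r in seq_len(nReps)) {
      repSeed <- (as.integer(seed) * 997L + pi * 131L + r) %% 2147483647L
      sim <- simulateProfile(simConfig(purities[pi], nBins = nBins,
                                       baseRD = baseRD, seed = repSeed))
      res <- tryCatch(
        runPipeline(profile = sim$profile, level = level,
                    seed = repSeed + 1L),
        puracnTooFewLosses = function(e) NULL)
      if (is.null(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          purity = purities[pi], rep = r, alphaHat = NA_real_,
          purityError = NA_real_, cnAccuracy = 0,
          nMatched = 0L, nSegments = length(sim$truth@segments),
          nLosses = 0L)
        next
      }
      ev <- evaluateEstimate(res$estimate, res$calls, sim$truth)
      rows[[length(rows) + 1L]] <- data.frame(
        purity = purities[pi], rep = r,
        alphaHat = res$estimate@alphaHat,
        purityError = ev$purityError, cnAccuracy = ev$cnAccuracy,
        nMatched = ev$nMatched, nSegments = ev$nSegments,
        nLosses = length(res$estimate@BHat))
    }
  }
  do.call(rbind, rows)
}
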