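#' @import methods
#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end width
#'   findOverlaps pintersect reduce sort.GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

#' RDProfile: a binned read-depth profile
#'
#' Container for a per-bin read-depth (RD) profile over genome coordinates:
#' an ordered set of fixed-size, non-overlapping genome bins, each carrying
#' its GC fraction, raw and (after [correctGCBias()]) corrected read depth,
#' and a mask flag for N-dominated bins.  The genome-wide mean RD over
#' unmasked bins (see [meanRD()]) is the reference level for a diploid,
#' copy-number-neutral genome and anchors both CNV direction calls and the
#' purity model.
#'
#' @slot bins A [GenomicRanges::GRanges] with one range per bin, sorted and
#'   non-overlapping, carrying metadata columns `gc` (GC fraction in
#'   \[0,1\]), `rd` (current, possibly GC-corrected, read depth), `rd_raw`
#'   (read count as extracted from the alignment), `n_frac` (fraction of N
#'   bases in the reference window) and `masked` (logical).
#' @slot binSize Integer bin width in bp; the last bin of a chromosome may
#'   be shorter.
#'
#' @seealso [binReadCounts()], [maskNBins()], [correctGCBias()], [meanRD()]
#' @export
setClass("RDProfile",
  representation(bins = "GRanges", binSize = "integer"))

setValidity("RDProfile", function(object) {
  b <- object@bins
  msg <- character()
  need <- c("gc", "rd", "rd_raw", "masked")
  if (!all(need %in% colnames(mcols(b))))
    msg <- c(msg, paste("bins must carry metadata columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(mcols(b)$rd < 0, na.rm = TRUE)) msg <- c(msg, "rd must be >= 0")
    gc <- mcols(b)$gc
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) msg <- c(msg, "gc must lie in [0,1]")
    if (!is.logical(mcols(b)$masked)) msg <- c(msg, "masked must be logical")
  }
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (length(b) > 1L) {
    if (!S4Vectors::isSorted(b))
      msg <- c(msg, "bins must be sorted by (chrom, start)")
    if (max(GenomicRanges::countOverlaps(b, b)) > 1L)
      msg <- c(msg, "bins must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' PurityEstimate: result of the exhaustive purity grid search
#'
#' Holds the full deviation curve d(alpha) over the candidate purity grid
#' together with the arg-min solution.  The deviation at each candidate
#' alpha is the mean absolute difference between the observed RDs of the
#' loss regions and the RDs the admixture model expects once the losses are
#' classified into homozygous (label 0) and heterozygous (label 1) at that
#' alpha.
#'
#' @slot alphaGrid Numeric vector of candidate purities (default
#'   0.05--0.95, step 0.01).
#' @slot deviations Numeric vector, the deviation d at each candidate.
#' @slot alphaHat The smallest alpha attaining the minimum deviation.
#' @slot dMin The minimum deviation.
#' @slot BHat Integer 0/1 labels of the loss regions at `alphaHat`
#'   (0 = homozygous loss, 1 = heterozygous loss).
#' @slot R Numeric vector of the observed loss-region RDs used.
#' @slot rBar The genome-wide mean RD used.
#'
#' @seealso [gridSearchPurity()]
#' @export
setClass("PurityEstimate",
  representation(alphaGrid = "numeric", deviations = "numeric",
                 alphaHat = "numeric", dMin = "numeric",
                 BHat = "integer", R = "numeric", rBar = "numeric"))

setValidity("PurityEstimate", function(object) {
  msg <- character()
  if (length(object@alphaGrid) != length(object@deviations))
    msg <- c(msg, "alphaGrid and deviations must have equal length")
  if (length(object@deviations) && any(object@deviations < 0))
    msg <- c(msg, "deviations must be >= 0")
  if (length(object@alphaHat) == 1L && length(object@alphaGrid) &&
      !any(abs(object@alphaGrid - object@alphaHat) < 1e-12))
    msg <- c(msg, "alphaHat must be a grid point")
  if (!all(object@BHat %in% c(0L, 1L)))
    msg <- c(msg, "BHat must contain only 0s and 1s")
  if (length(msg)) msg else TRUE
})

#' LossSet: observed read depths of copy-number-loss regions
#'
#' The input to purity inference: one observed RD per loss region (the
#' region's mean corrected RD), all strictly below the genome-wide mean RD.
#'
#' @slot regions A `GRanges` of the loss regions (may be empty when the
#'   set is built from bare RD values).
#' @slot R Numeric vector of observed RDs, one per region.
#'
#' @seealso [lossSet()], [gridSearchPurity()]
#' @export
setClass("LossSet",
  representation(regions = "GRanges", R = "numeric"))

setValidity("LossSet", function(object) {
  if (length(object@regions) && length(object@regions) != length(object@R))
    "length(R) must equal the number of regions" else TRUE
})

#' SimTruth: ground truth of a synthetic admixed profile
#'
#' @slot purity True tumor purity alpha of the simulated admixture.
#' @slot segments `GRanges` of planted CNV segments with metadata column
#'   `cn` (integer tumor copy number).
#' @slot expectedRD Numeric per-bin expected RD under the mixture model
#'   baseRD * (purity * cn + 2 * (1 - purity)) / 2.
#' @slot baseRD Mean RD of a copy-number-neutral bin.
#'
#' @seealso [simulateProfile()], [evaluateEstimate()]
#' @export
setClass("SimTruth",
  representation(purity = "numeric", segments = "GRanges",
                 expectedRD = "numeric", baseRD = "numeric"))
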