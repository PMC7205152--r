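#' @importFrom Rsamtools BamFile FaFile scanBam ScanBamParam scanBamFlag
#'   scanBamHeader indexFa scanFaIndex
#' @importFrom Biostrings getSeq letterFrequency
#' @importFrom GenomeInfoDb seqlengths seqnames
#' @importFrom stats median setNames
NULL

.newRDProfile <- function(bins, binSize) {
  new("RDProfile", bins = bins, binSize = as.integer(binSize))
}

.tileContig <- function(chrom, len, binSize) {
  starts <- seq.int(1L, len, by = binSize)
  ends <- pmin(starts + binSize - 1L, len)
  GRanges(chrom, IRanges(start = starts, end = ends))
}

#' Bin read counts from an alignment file
#'
#' Extracts a binned read-count profile from a coordinate-sorted, indexed
#' BAM file.  The genome is divided into non-overlapping windows of
#' `binSize` bp (the last window of a chromosome may be shorter) and each
#' retained read is assigned to exactly one bin by its leftmost mapped
#' position.  Unmapped, secondary, supplementary and duplicate-flagged
#' reads are excluded, so the per-bin counts sum to the number of retained
#' alignments.  The GC fraction and N fraction of every window are computed
#' from the reference.
#'
#' @param alignmentPath Path to a coordinate-sorted BAM with a `.bai` index.
#' @param referencePath Path to the reference FASTA (a `.fai` index is
#'   created if absent).
#' @param binSize Window size in bp (default 1000).
#' @return An [RDProfile-class] with per-bin `rd` equal to the raw read
#'   count (`rd_raw` holds a copy for later comparison with the
#'   GC-corrected values), `gc` the G+C fraction of the non-N reference
#'   bases, `n_frac` the N fraction, and `masked = FALSE` everywhere.
#' @examples
#' \dontrun{
#' prof <- binReadCounts("tumor.bam", "hg19.fa", binSize = 1000)
#' }
#' @export
binReadCounts <- function(alignmentPath, referencePath, binSize = 1000L) {
  binSize <- as.integer(binSize)
  stopifnot(binSize >= 1L)
  if (!file.exists(alignmentPath))
    stop("alignment file not found: ", alignmentPath)
  idx <- paste0(alignmentPath, ".bai")
  idx2 <- sub("\\.bam$", ".bai", alignmentPath)
  if (!file.exists(idx) && !file.exists(idx2))
    stop("BAM index not found for '", alignmentPath,
         "'; create one with samtools index (or Rsamtools::indexBam)")
  if (!file.exists(referencePath))
    stop("reference FASTA not found: ", referencePath)
  if (!file.exists(paste0(referencePath, ".fai")))
    indexFa(referencePath)
  fa <- FaFile(referencePath)
  refInfo <- scanFaIndex(fa)
  refLens <- setNames(width(refInfo), as.character(seqnames(refInfo)))

  bf <- BamFile(alignmentPath)
  targets <- scanBamHeader(bf)$targets
  flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                      isSupplementaryAlignment = FALSE,
                      isDuplicate = FALSE)
  aln <- scanBam(bf, param = ScanBamParam(flag = flag,
                                          what = c("rname", "pos")))[[1]]
  keep <- !is.na(aln$pos)
  rname <- as.character(aln$rname)[keep]
  pos <- aln$pos[keep]
  if (length(pos) == 0L)
    stop("no mapped reads in ", alignmentPath)

  used <- names(targets)
  missing <- setdiff(used, names(refLens))
  if (length(missing))
    stop("contig(s) absent from reference: ", paste(missing, collapse = ", "))
  bad <- used[targets[used] > refLens[used]]
  if (length(bad))
    stop("contig(s) longer in alignment header than in reference: ",
         paste(bad, collapse = ", "))

  grl <- lapply(used, function(chrom) {
    gr <- .tileContig(chrom, refLens[[chrom]], binSize)
    p <- pos[rname == chrom]
    counts <- tabulate((p - 1L) %/% binSize + 1L, nbins = length(gr))
    mcols(gr)$rd_raw <- as.numeric(counts)
    gr
  })
  allBins <- do.call(c, grl)

  seqs <- getSeq(fa, allBins)
  freq <- letterFrequency(seqs, c("A", "C", "G", "T", "N"))
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt, 0)
  mcols(allBins)$gc <- as.numeric(gc)
  mcols(allBins)$n_frac <- as.numeric(freq[, "N"] / width(allBins))
  mcols(allBins)$rd <- mcols(allBins)$rd_raw
  mcols(allBins)$masked <- rep(FALSE, length(allBins))
  .newRDProfile(allBins, binSize)
}

#' Mask N-dominated bins
#'
#' Bins whose reference N fraction exceeds `nFracThreshold` are excluded
#' from the mean-RD statistic and from CNV detection.  By default they are
#' flagged `masked`; with `fill = "mean"` they are instead filled with the
#' mean RD of the remaining bins and left unmasked (both treatments are in
#' common use; masking avoids fabricating signal and is the default).
#' The operation is idempotent.
#'
#' @param profile An [RDProfile-class] (its `n_frac` column, populated by
#'   [binReadCounts()] or [simulateProfile()], drives the decision).
#' @param nFracThreshold Bins with N fraction strictly greater than this are
#'   affected; `1.0` disables masking.  Default 0.5.
#' @param fill `"mask"` (default) or `"mean"`.
#' @return The updated [RDProfile-class].
#' @export
maskNBins <- function(profile, nFracThreshold = 0.5, fill = c("mask", "mean")) {
  fill <- match.arg(fill)
  stopifnot(is(profile, "RDProfile"),
            nFracThreshold >= 0, nFracThreshold <= 1)
  b <- profile@bins
  nf <- mcols(b)$n_frac
  if (is.null(nf))
    stop("profile carries no n_frac column; run binReadCounts() first")
  hit <- nf > nFracThreshold
  if (fill == "mask") {
    mcols(b)$masked <- mcols(b)$masked | hit
  } else {
    keep <- !hit & !mcols(b)$masked
    if (!any(keep))
      stop("maskNBins: no bins left to compute the fill value from")
    mcols(b)$rd[hit] <- mean(mcols(b)$rd[keep])
  }
  .newRDProfile(b, profile@binSize)
}

.gcStratum <- function(gc) pmin(floor(gc * 100), 99L)

#' Correct GC-content bias
#'
#' Rescales each unmasked bin's RD by the ratio of the global median RD to
#' the median RD of the bin's GC stratum (1%-wide GC intervals) -- the
#' standard median-ratio normalization for coverage-vs-GC bias.  Strata
#' with fewer than `minStratumBins` unmasked bins (or a zero median) borrow
#' the correction factor of the nearest adequately populated stratum, so
#' sparse GC extremes are not rescaled by an unstable median.  Masked bins
#' are untouched.
#'
#' @param profile An [RDProfile-class].
#' @param minStratumBins Minimum unmasked bins a stratum needs to use its
#'   own median (default 20).
#' @return The profile with `rd` rescaled (`rd_raw` keeps the input values).
#' @export
correctGCBias <- function(profile, minStratumBins = 20L) {
  stopifnot(is(profile, "RDProfile"))
  b <- profile@bins
  ok <- !mcols(b)$masked
  if (!any(ok))
    stop("correctGCBias: all bins are masked")
  rd <- mcols(b)$rd[ok]
  strat <- .gcStratum(mcols(b)$gc[ok])
  globalMed <- median(rd)
  med <- tapply(rd, strat, median)
  cnt <- tapply(rd, strat, length)
  lv <- as.integer(names(med))
  good <- cnt >= minStratumBins & med > 0
  factors <- rep(NA_real_, length(lv))
  factors[good] <- globalMed / med[good]
  if (!any(good)) {
    # profile too small for stratified correction: leave it unchanged
    factors[] <- 1
  } else if (any(!good)) {
    for (i in which(!good)) {
      j <- which(good)[which.min(abs(lv[which(good)] - lv[i]))]
      factors[i] <- factors[j]
    }
  }
  f <- factors[match(strat, lv)]
  mcols(b)$rd[ok] <- rd * f
  .newRDProfile(b, profile@binSize)
}

#' Write / read a read-depth profile as TSV
#'
#' The on-disk format is a tab-separated table with a header line and
#' columns `chrom`, `start`, `end` (0-based half-open), `gc`, `n_frac`,
#' `rd_raw`, `rd_corrected`, `masked`; coordinates are plain integers,
#' never scientific notation.
#'
#' @param profile An [RDProfile-class].
#' @param path Output (or input) file path.
#' @return `writeRDProfile` returns `path` invisibly; `readRDProfile`
#'   returns an [RDProfile-class].
#' @export
writeRDProfile <- function(profile, path) {
  stopifnot(is(profile, "RDProfile"))
  b <- profile@bins
  df <- data.frame(
    chrom = as.character(seqnames(b)),
    start = format(start(b) - 1L, scientific = FALSE, trim = TRUE),
    end = format(end(b), scientific = FALSE, trim = TRUE),
    gc = mcols(b)$gc,
    n_frac = if (is.null(mcols(b)$n_frac)) 0 else mcols(b)$n_frac,
    rd_raw = mcols(b)$rd_raw,
    rd_corrected = mcols(b)$rd,
    masked = as.integer(mcols(b)$masked),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeRDProfile
#' @export
readRDProfile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "rd_corrected")
  if (!all(need %in% names(df)))
    stop("profile TSV must have columns: ", paste(need, collapse = ", "))
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
  mcols(gr)$gc <- if (is.null(df$gc)) rep(0.5, nrow(df)) else df$gc
  mcols(gr)$n_frac <- if (is.null(df$n_frac)) rep(0, nrow(df)) else df$n_frac
  mcols(gr)$rd_raw <- if (is.null(df$rd_raw)) df$rd_corrected else df$rd_raw
  mcols(gr)$rd <- df$rd_corrected
  mcols(gr)$masked <- if (is.null(df$masked)) rep(FALSE, nrow(df))
                      else as.logical(df$masked)
  binSize <- max(df$end - df$start)
  .newRDProfile(gr, binSize)
}
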