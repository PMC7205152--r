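#' @importFrom stats pgamma var sd p.adjust runif rpois rnbinom
NULL

#' Significance test of smoothed anomaly scores against a Gamma fit
#'
#' Fits a Gamma distribution to the smoothed per-bin anomaly scores by the
#' method of moments (shape = m^2/v, scale = v/m) and converts each score
#' to an upper-tail probability; a bin is flagged as CNV when its p-value
#' falls below `level`.  High anomaly scores — RDs far from the bulk in
#' either direction — land in the upper tail, so only that tail is tested;
#' gain/loss direction is assigned later from the RD itself.  Scores at or
#' below zero are handled by shifting the whole vector just above zero
#' before fitting.
#'
#' @param smoothed Numeric vector of smoothed scores.
#' @param level Significance level (default 0.01).
#' @param adjust `"none"` (default: raw p-values are thresholded) or
#'   `"BH"` for Benjamini-Hochberg adjustment before thresholding.
#' @return A list with elements `pvalue` (numeric), `call` (logical),
#'   `shape`, `scale` and `level`.
#' @export
gammaTest <- function(smoothed, level = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.numeric(smoothed), length(smoothed) >= 2L,
            level >= 0, level <= 1)
  if (any(!is.finite(smoothed))) stop("smoothed scores must be finite")
  x <- smoothed
  if (min(x) <= 0)
    x <- x - min(x) + 1e-9
  m <- mean(x); v <- var(x)
  if (v == 0) {
    warning("zero-variance scores: no CNV calls")
    return(list(pvalue = rep(1, length(x)), call = rep(FALSE, length(x)),
                shape = NA_real_, scale = NA_real_, level = level))
  }
  shape <- m^2 / v
  scale <- v / m
  p <- pgamma(x, shape = shape, scale = scale, lower.tail = FALSE)
  padj <- if (adjust == "BH") p.adjust(p, method = "BH") else p
  list(pvalue = p, call = padj < level, shape = shape, scale = scale,
       level = level)
}

# keep weak-threshold runs only when they contain a strong seed bin
.hysteresis <- function(strong, weak, chrom) {
  grp <- cumsum(c(TRUE, diff(as.integer(weak)) != 0 |
                        chrom[-1] != chrom[-length(chrom)]))
  keepGrp <- unique(grp[strong & weak])
  (weak & grp %in% keepGrp) | strong
}

.emptyCNVRegions <- function() {
  gr <- GRanges()
  mcols(gr)$direction <- character(0)
  mcols(gr)$observed_rd <- numeric(0)
  mcols(gr)$n_bins <- integer(0)
  mcols(gr)$p_best <- numeric(0)
  gr
}

#' Merge flagged bins into directional CNV regions
#'
#' Maximal runs of consecutively flagged unmasked bins on one chromosome
#' become one region (masked bins were removed from the sequence before
#' detection and do not break a run).  A region's observed RD is the mean
#' corrected RD of its member bins; direction is `loss` when that mean is
#' below the genome-wide mean RD `rBar` and `gain` when above.  A region
#' whose mean equals `rBar` exactly carries no direction and is dropped
#' with a warning.
#'
#' @param flags Logical per-unmasked-bin CNV flags (e.g. `call` from
#'   [gammaTest()]).
#' @param profile The [RDProfile-class] the flags refer to.
#' @param rBar Genome-wide mean RD (default [meanRD()] of the profile).
#' @param pvalue Optional per-unmasked-bin p-values; each region then
#'   records `p_best`, the smallest p among its bins.
#' @return A `GRanges` with metadata columns `direction`, `observed_rd`,
#'   `n_bins` and `p_best`.
#' @export
mergeCalls <- function(flags, profile, rBar = meanRD(profile),
                       pvalue = NULL) {
  stopifnot(is(profile, "RDProfile"), is.logical(flags))
  b <- profile@bins[!mcols(profile@bins)$masked]
  if (length(flags) != length(b))
    stop("flags must align with the profile's unmasked bins (",
         length(b), " bins, ", length(flags), " flags)")
  if (!is.null(pvalue) && length(pvalue) != length(b))
    stop("pvalue must align with the profile's unmasked bins")
  if (!any(flags)) return(.emptyCNVRegions())
  chrom <- as.character(seqnames(b))
  grp <- cumsum(c(TRUE, diff(as.integer(flags)) != 0 |
                        chrom[-1] != chrom[-length(chrom)]))
  rows <- list()
  for (g in unique(grp[flags])) {
    i <- which(grp == g)
    rd <- mean(mcols(b)$rd[i])
    if (rd == rBar) {
      warning("region at ", chrom[i[1]], ":", start(b)[i[1]] - 1L, "-",
              end(b)[i[length(i)]], " has mean RD equal to rBar; dropped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom[i[1]], start = start(b)[i[1]],
      end = end(b)[i[length(i)]],
      direction = if (rd < rBar) "loss" else "gain",
      observed_rd = rd, n_bins = length(i),
      p_best = if (is.null(pvalue)) NA_real_ else min(pvalue[i]))
  }
  if (length(rows) == 0L) return(.emptyCNVRegions())
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(start = df$start, end = df$end))
  mcols(gr) <- DataFrame(df[c("direction", "observed_rd", "n_bins",
                              "p_best")])
  sort(gr)
}

#' Import externally called CNV regions from a BED file
#'
#' The detector stage can be replaced by any external CNV caller: this
#' reads its calls from a 3+ column BED (0-based half-open) and attaches
#' the observed RD of every region from the profile's overlapping unmasked
#' bins.  An optional 4th (name) column equal to `gain` or `loss` fixes the
#' direction; otherwise direction comes from comparing the observed RD to
#' `rBar`.
#'
#' @param path BED file of regions.
#' @param profile The [RDProfile-class] providing RDs.
#' @param rBar Genome-wide mean RD (default [meanRD()] of the profile).
#' @return A `GRanges` as from [mergeCalls()].  Records overlapping no
#'   unmasked bin are skipped with a warning.
#' @export
loadExternalCalls <- function(path, profile, rBar = meanRD(profile)) {
  stopifnot(is(profile, "RDProfile"))
  if (!file.exists(path)) stop("CNV file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  if (!any(keep)) return(.emptyCNVRegions())
  fields <- strsplit(lines[keep], "\\s+")
  lineno <- which(keep)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L || anyNA(suppressWarnings(as.numeric(f[2:3]))))
      stop("malformed BED record at line ", lineno[i], " of ", path)
  }
  calls <- rtracklayer::import(path, format = "BED")
  b <- profile@bins[!mcols(profile@bins)$masked]
  known <- unique(as.character(seqnames(b)))
  bad <- setdiff(unique(as.character(seqnames(calls))), known)
  if (length(bad))
    stop("CNV record on contig(s) absent from profile: ",
         paste(bad, collapse = ", "))
  hits <- findOverlaps(calls, b)
  out <- list()
  for (i in seq_along(calls)) {
    j <- subjectHits(hits)[queryHits(hits) == i]
    if (length(j) == 0L) {
      warning("region ", as.character(seqnames(calls))[i], ":",
              start(calls)[i] - 1L, "-", end(calls)[i],
              " overlaps no unmasked bin; skipped")
      next
    }
    rd <- mean(mcols(b)$rd[j])
    dir <- mcols(calls)$name[i]
    if (is.null(dir) || is.na(dir) || !dir %in% c("gain", "loss")) {
      if (rd == rBar) {
        warning("region ", as.character(seqnames(calls))[i], ":",
                start(calls)[i] - 1L, "-", end(calls)[i],
                " has mean RD equal to rBar; dropped")
        next
      }
      dir <- if (rd < rBar) "loss" else "gain"
    }
    gr <- calls[i]
    mcols(gr) <- NULL
    mcols(gr)$direction <- dir
    mcols(gr)$observed_rd <- rd
    mcols(gr)$n_bins <- length(j)
    mcols(gr)$p_best <- NA_real_
    out[[length(out) + 1L]] <- gr
  }
  if (length(out) == 0L) return(.emptyCNVRegions())
  sort(do.call(c, out))
}

#' Detect CNV regions from a read-depth profile
#'
#' The full anomaly-score detector: per-bin isolation-forest scores on the
#' GC-corrected RDs of unmasked bins, total-variation smoothing per
#' chromosome, Gamma upper-tail significance testing, and merging of
#' flagged bins into directional regions.
#'
#' @param profile A GC-corrected [RDProfile-class].
#' @param level Per-bin significance level (default 0.01).
#' @param nTrees,subsample Isolation-forest size (defaults 256 and 256).
#' @param lam TV penalty; `NULL` (default) uses `2 * sd(raw scores)`,
#'   strong enough that isolated noisy bins are absorbed into their
#'   neighbourhood while multi-bin aberrant segments (which lose only
#'   `2*lam/length` in height) survive essentially intact.
#' @param seed Integer seed for the forest subsampling and splits.
#' @param adjust Multiple-testing adjustment passed to [gammaTest()].
#' @param levelExtend Secondary (relaxed) significance level for
#'   hysteresis region growing: a contiguous run of bins with
#'   `p < levelExtend` is called only when it contains at least one bin
#'   with `p < level`.  This recovers the full extent of weak aberrant
#'   segments whose plateau straddles the primary threshold without
#'   admitting isolated noise (which lacks a seed bin).  Default
#'   `10 * level`; set equal to `level` to disable.
#' @return A list with `regions` (a `GRanges` as from [mergeCalls()]) and
#'   `scores` (a `data.frame` with per-unmasked-bin `raw`, `smoothed`,
#'   `pvalue`, `call`).
#' @export
detectCNV <- function(profile, level = 0.01, nTrees = 256L, subsample = 256L,
                      lam = NULL, seed = NULL, adjust = c("none", "BH"),
                      levelExtend = 10 * level) {
  stopifnot(is(profile, "RDProfile"))
  adjust <- match.arg(adjust)
  b <- profile@bins[!mcols(profile@bins)$masked]
  if (length(b) < 2L) stop("detectCNV: need at least 2 unmasked bins")
  rd <- mcols(b)$rd
  forest <- buildIsolationForest(rd, nTrees = nTrees, subsample = subsample,
                                 seed = seed)
  raw <- anomalyScores(forest, rd)
  if (is.null(lam)) lam <- 2 * sd(raw)
  smoothed <- tvDenoise(raw, lam, chrom = as.character(seqnames(b)))
  gt <- gammaTest(smoothed, level = level, adjust = adjust)
  call <- gt$call
  if (levelExtend > level && any(call)) {
    chrom <- as.character(seqnames(b))
    call <- .hysteresis(call, gt$pvalue < levelExtend, chrom)
  }
  regions <- mergeCalls(call, profile, pvalue = gt$pvalue)
  list(regions = regions,
       scores = data.frame(raw = raw, smoothed = smoothed,
                           pvalue = gt$pvalue, call = gt$call))
}

#' Write CNV calls as BED6 and TSV
#'
#' @param regions A `GRanges` of CNV regions (from [mergeCalls()],
#'   [loadExternalCalls()] or [absoluteCopyNumber()]).
#' @param bedPath Output BED6 path (`name` = direction, `score` =
#'   `-10*log10(p_best)` capped at 3000, strand `"."`); `NULL` to skip.
#' @param tsvPath Output TSV path with `observed_rd` and `n_bins` (and CN
#'   columns when present); `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
writeCNVCalls <- function(regions, bedPath = NULL, tsvPath = NULL) {
  chrom <- as.character(seqnames(regions))
  s0 <- start(regions) - 1L
  e <- end(regions)
  if (!is.null(bedPath)) {
    p <- mcols(regions)$p_best
    score <- ifelse(is.na(p) | p <= 0, 3000, pmin(3000, -10 * log10(p)))
    bed <- data.frame(chrom,
                      format(s0, scientific = FALSE, trim = TRUE),
                      format(e, scientific = FALSE, trim = TRUE),
                      mcols(regions)$direction, round(score, 2), ".")
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsvPath)) {
    df <- data.frame(chrom = chrom,
                     start = format(s0, scientific = FALSE, trim = TRUE),
                     end = format(e, scientific = FALSE, trim = TRUE),
                     direction = mcols(regions)$direction,
                     observed_rd = mcols(regions)$observed_rd,
                     n_bins = mcols(regions)$n_bins)
    for (col in c("cn_real", "cn_int"))
      if (!is.null(mcols(regions)[[col]])) df[[col]] <- mcols(regions)[[col]]
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(c(bed = bedPath, tsv = tsvPath))
}
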