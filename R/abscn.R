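# Conversion of observed region RDs to absolute copy numbers at the
# estimated purity: deconvolve to the pure-tumor RD, then scale by the
# diploid reference level (rBar corresponds to copy number 2).

#' Round a continuous copy number to a non-negative integer
#'
#' Round-half-up (3.5 -> 4), floored at 0 so noise-driven small negative
#' values map to 0.
#'
#' @param cnReal Numeric vector of continuous copy numbers.
#' @return Integer vector.
#' @examples
#' roundCN(c(3.5, -0.2, 7.96))  # 4 0 8
#' @export
roundCN <- function(cnReal) {
  if (any(!is.finite(cnReal))) stop("cnReal must be finite")
  as.integer(pmax(0, floor(cnReal + 0.5)))
}

#' Infer absolute copy numbers of CNV regions
#'
#' For every region (losses and gains alike) the observed mean RD is
#' deconvolved to the pure-tumor absolute RD
#' `q = (observed_rd - (1 - alpha) * rBar) / alpha`, clipped at 0 so noise
#' cannot produce negative copy numbers, and scaled to copy-number units
#' via `cn_real = 2 * q / rBar` (rBar corresponds to the diploid state).
#' `cn_int` is the round-half-up integer copy number.
#'
#' @param regions A `GRanges` of CNV regions with an `observed_rd` column
#'   (as produced by [mergeCalls()] or [loadExternalCalls()]), or a bare
#'   numeric vector of observed RDs.
#' @param alpha Estimated tumor purity in (0, 1].
#' @param rBar Genome-wide mean RD.
#' @return For `GRanges` input, the same ranges with added metadata
#'   columns `q`, `cn_real`, `cn_int`; for numeric input, a `data.frame`
#'   with columns `observed_rd`, `q`, `cn_real`, `cn_int`.
#' @examples
#' absoluteCopyNumber(c(15, 5, 7.5), alpha = 0.5, rBar = 10)
#' @export
absoluteCopyNumber <- function(regions, alpha, rBar) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (!is.numeric(rBar) || length(rBar) != 1L || rBar <= 0)
    stop("rBar must be a single positive value")
  rd <- if (is(regions, "GRanges")) mcols(regions)$observed_rd else regions
  if (is.null(rd) || !is.numeric(rd))
    stop("regions must carry numeric observed RDs")
  q <- pmax(0, recoverAbsoluteRD(rd, alpha, rBar))
  cnReal <- 2 * q / rBar
  cnInt <- roundCN(cnReal)
  if (is(regions, "GRanges")) {
    mcols(regions)$q <- q
    mcols(regions)$cn_real <- cnReal
    mcols(regions)$cn_int <- cnInt
    regions
  } else {
    data.frame(observed_rd = rd, q = q, cn_real = cnReal, cn_int = cnInt)
  }
}

#' Write the final copy-number report
#'
#' TSV with columns `chrom`, `start`, `end`, `direction`, `observed_rd`,
#' `cn_real`, `cn_int`, preceded by comment lines carrying the purity
#' summary (`# alpha_hat=`, `# d_min=`).
#'
#' @param regions A `GRanges` from [absoluteCopyNumber()].
#' @param path Output path.
#' @param estimate Optional [PurityEstimate-class] for the header.
#' @return `path`, invisibly.
#' @export
writeCNReport <- function(regions, path, estimate = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(estimate))
    writeLines(c(sprintf("# alpha_hat=%.2f", estimate@alphaHat),
                 sprintf("# d_min=%.8g", estimate@dMin)), con)
  df <- data.frame(
    chrom = as.character(seqnames(regions)),
    start = format(start(regions) - 1L, scientific = FALSE, trim = TRUE),
    end = format(end(regions), scientific = FALSE, trim = TRUE),
    direction = mcols(regions)$direction,
    observed_rd = mcols(regions)$observed_rd,
    cn_real = mcols(regions)$cn_real,
    cn_int = mcols(regions)$cn_int)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
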