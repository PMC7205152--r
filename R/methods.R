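#' @describeIn RDProfile-class The `GRanges` of bins.
#' @export
setMethod("bins", "RDProfile", function(x) x@bins)

#' @describeIn RDProfile-class Configured bin width in bp.
#' @export
setMethod("binSize", "RDProfile", function(x) x@binSize)

#' @describeIn meanRD Mean RD over unmasked bins; errors when no unmasked
#'   bin remains or the mean is zero (an all-zero profile cannot anchor the
#'   admixture model, which divides by the mean RD).
#' @export
setMethod("meanRD", "RDProfile", function(x, ...) {
  rd <- mcols(x@bins)$rd[!mcols(x@bins)$masked]
  if (length(rd) == 0L)
    stop("meanRD: no unmasked bins in profile")
  m <- mean(rd)
  if (!is.finite(m) || m <= 0)
    stop("meanRD: mean read depth over unmasked bins is not positive ",
         "(all-zero or invalid profile)")
  m
})

#' @export
setMethod("show", "RDProfile", function(object) {
  b <- object@bins
  cat("RDProfile with", length(b), "bins of", object@binSize, "bp on",
      length(unique(as.character(seqnames(b)))), "sequence(s)\n")
  cat("  masked bins:", sum(mcols(b)$masked), "\n")
  ok <- !mcols(b)$masked
  if (any(ok))
    cat(sprintf("  mean RD (unmasked): %.4g\n", mean(mcols(b)$rd[ok])))
  invisible(NULL)
})

#' @describeIn PurityEstimate-class Estimated tumor purity (arg-min alpha).
#' @export
setMethod("alphaHat", "PurityEstimate", function(x) x@alphaHat)

#' @describeIn PurityEstimate-class The deviation curve as a data.frame
#'   with columns `alpha` and `deviation`.
#' @export
setMethod("deviations", "PurityEstimate", function(x)
  data.frame(alpha = x@alphaGrid, deviation = x@deviations))

#' @describeIn PurityEstimate-class Integer 0/1 loss labels at the
#'   estimated purity (0 = homozygous, 1 = heterozygous).
#' @export
setMethod("lossLabels", "PurityEstimate", function(x) x@BHat)

#' @export
setMethod("show", "PurityEstimate", function(object) {
  cat("PurityEstimate\n")
  cat(sprintf("  alpha_hat = %.2f   (grid %.2f..%.2f, %d candidates)\n",
              object@alphaHat, min(object@alphaGrid), max(object@alphaGrid),
              length(object@alphaGrid)))
  cat(sprintf("  min deviation = %.6g\n", object@dMin))
  cat(sprintf("  loss regions: %d (%d homozygous, %d heterozygous)\n",
              length(object@BHat), sum(object@BHat == 0L),
              sum(object@BHat == 1L)))
  invisible(NULL)
})

#' @export
setMethod("show", "LossSet", function(object) {
  cat("LossSet with", length(object@R), "loss regions\n")
  if (length(object@R))
    cat(sprintf("  observed RD range: [%.4g, %.4g]\n",
                min(object@R), max(object@R)))
  invisible(NULL)
})

#' @export
setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: purity %.2f, %d planted segments, baseRD %.4g\n",
              object@purity, length(object@segments), object@baseRD))
  invisible(NULL)
})

#' @rdname LossSet-class
#' @export
setMethod("length", "LossSet", function(x) length(x@R))
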