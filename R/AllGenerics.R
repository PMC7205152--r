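#' @rdname RDProfile-class
#' @param x,object An object.
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname RDProfile-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Genome-wide mean read depth
#'
#' Arithmetic mean of the (current, i.e. GC-corrected if
#' [correctGCBias()] has run) read depth over unmasked bins.  This is the
#' RD level attributed to the diploid, copy-number-neutral state: CNVs
#' occupy a small fraction of the genome and include both directions of
#' change, so the global mean is taken to approximate the normal-copy RD.
#'
#' @param x An [RDProfile-class].
#' @param ... Unused.
#' @return A single positive number.
#' @export
setGeneric("meanRD", function(x, ...) standardGeneric("meanRD"))

#' @rdname PurityEstimate-class
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))

#' @rdname PurityEstimate-class
#' @export
setGeneric("deviations", function(x) standardGeneric("deviations"))

#' @rdname PurityEstimate-class
#' @export
setGeneric("lossLabels", function(x) standardGeneric("lossLabels"))
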