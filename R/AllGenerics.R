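#' @rdname CdsSet-class
#' @param x A `CdsSet`.
#' @export
setGeneric("cdsSequences", function(x) standardGeneric("cdsSequences"))

#' @rdname CdsSet-class
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname CoaResult-class
#' @param x A `CoaResult`.
#' @export
setGeneric("geneCoords", function(x) standardGeneric("geneCoords"))

#' @rdname CoaResult-class
#' @export
setGeneric("codonCoords", function(x) standardGeneric("codonCoords"))

#' @rdname CoaResult-class
#' @export
setGeneric("inertiaFractions", function(x) standardGeneric("inertiaFractions"))

#' @rdname ContextMatrix-class
#' @param x A `ContextMatrix`.
#' @export
setGeneric("observedPairs", function(x) standardGeneric("observedPairs"))

#' @rdname ContextMatrix-class
#' @export
setGeneric("expectedPairs", function(x) standardGeneric("expectedPairs"))

#' @rdname ContextMatrix-class
#' @export
setGeneric("pairResiduals", function(x) standardGeneric("pairResiduals"))
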