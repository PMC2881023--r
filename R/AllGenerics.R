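#' @rdname strainInfo
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @rdname strainInfo
#' @export
setGeneric("collectiveMap", function(x) standardGeneric("collectiveMap"))

#' @rdname simTruth
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname contrastResults
#' @export
setGeneric("contrastResults",
           function(x, strain = NULL) standardGeneric("contrastResults"))

#' @rdname priorAccessors
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))

#' @rdname priorAccessors
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))
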