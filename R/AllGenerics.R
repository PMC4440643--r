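#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @export
setGeneric("cpgInfo", function(x) standardGeneric("cpgInfo"))

#' @export
setGeneric("clinicalInfo", function(x) standardGeneric("clinicalInfo"))

#' @export
setGeneric("tfNames", function(x) standardGeneric("tfNames"))

#' @export
setGeneric("motifWidths", function(x) standardGeneric("motifWidths"))

#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))
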