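#' @include AllClasses.R
NULL

#' @export
setGeneric("designCode", function(x) standardGeneric("designCode"))
#' @export
setGeneric("nFounders", function(x) standardGeneric("nFounders"))
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @export
setGeneric("chrNames", function(x) standardGeneric("chrNames"))
#' @export
setGeneric("genoMap", function(x) standardGeneric("genoMap"))
#' @export
setGeneric("probArray", function(x, chr) standardGeneric("probArray"))
#' @export
setGeneric("stateNames", function(x, chr) standardGeneric("stateNames"))
#' @export
setGeneric("lodMatrix", function(x) standardGeneric("lodMatrix"))
#' @export
setGeneric("phenoMatrix", function(x) standardGeneric("phenoMatrix"))
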