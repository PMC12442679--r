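#' @rdname SgRNALibrary-accessors
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname SgRNALibrary-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SgRNALibrary-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname SgRNALibrary-accessors
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname SgRNALibrary-accessors
#' @export
setGeneric("nTargeting", function(x) standardGeneric("nTargeting"))

#' @rdname SgRNALibrary-accessors
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @rdname guideAbundance
#' @export
setGeneric("guideAbundance", function(pop, ...) standardGeneric("guideAbundance"))
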