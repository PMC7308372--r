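#' @rdname CoexpressionNetwork-class
#' @param object,x a package object
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkNodes", function(x, ...) standardGeneric("networkNodes"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("candidateSet", function(x) standardGeneric("candidateSet"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("pCutoff", function(x) standardGeneric("pCutoff"))

#' @rdname TraitExperiment-class
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname TraitExperiment-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname TraitExperiment-class
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))

#' @rdname TraitExperiment-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname GroupPartition-class
#' @export
setGeneric("phenotypeGroups", function(x) standardGeneric("phenotypeGroups"))

#' @rdname NullTendencyProfile-class
#' @export
setGeneric("tendencyTable", function(x) standardGeneric("tendencyTable"))

#' @rdname NullTendencyProfile-class
#' @export
setGeneric("tendencyTests", function(x) standardGeneric("tendencyTests"))
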