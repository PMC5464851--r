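#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname missingMask
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname featureIds
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname subtypes
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' @rdname clusterAssignments
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname signatureMembers
#' @export
setGeneric("signatureMembers", function(x) standardGeneric("signatureMembers"))

#' @rdname dlcvMetrics
#' @export
setGeneric("dlcvMetrics", function(x) standardGeneric("dlcvMetrics"))

#' @rdname selectionFrequency
#' @export
setGeneric("selectionFrequency",
           function(x) standardGeneric("selectionFrequency"))
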