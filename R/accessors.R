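#' Expression values of a MirnaExpressionSet
#'
#' @param x A \linkS4class{MirnaExpressionSet}.
#' @return Numeric matrix, features x samples, log2 scale.
#' @export
#' @name exprValues
setMethod("exprValues", "MirnaExpressionSet", function(x)
  SummarizedExperiment::assay(x, "log2expr"))

#' Missing-value mask of a MirnaExpressionSet
#'
#' @param x A \linkS4class{MirnaExpressionSet}.
#' @return Logical matrix; \code{TRUE} where the value was undetected before
#'   imputation.
#' @export
#' @name missingMask
setMethod("missingMask", "MirnaExpressionSet", function(x)
  SummarizedExperiment::assay(x, "missing"))

#' Feature identifiers
#'
#' @param x A \linkS4class{MirnaExpressionSet}.
#' @return Character vector of miRNA (or gene) identifiers.
#' @export
#' @name featureIds
setMethod("featureIds", "MirnaExpressionSet", function(x) rownames(x))

#' Sample identifiers
#'
#' @param x A \linkS4class{MirnaExpressionSet} or
#'   \linkS4class{SampleAnnotation}.
#' @return Character vector of sample identifiers.
#' @export
#' @name sampleIds
setMethod("sampleIds", "MirnaExpressionSet", function(x) colnames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SampleAnnotation", function(x) rownames(x))

#' Subtype labels
#'
#' @param x A \linkS4class{SampleAnnotation}.
#' @return Factor of per-sample subtype tokens over
#'   \code{\link{AML_SUBTYPES}}.
#' @export
#' @name subtypes
setMethod("subtypes", "SampleAnnotation", function(x) x$subtype)

#' Flat cluster assignments
#'
#' @param x A \linkS4class{ClusterResult}.
#' @return Named integer vector of cluster indices in 1..k.
#' @export
#' @name clusterAssignments
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)

#' Members of a subtype signature
#'
#' @param x A \linkS4class{SubtypeSignature} or \linkS4class{DlcvResult}.
#' @return data.frame with columns \code{mirna}, \code{direction},
#'   \code{frequency}, sorted by descending frequency.
#' @export
#' @name signatureMembers
setMethod("signatureMembers", "SubtypeSignature", function(x) x@members)

#' @rdname signatureMembers
#' @export
setMethod("signatureMembers", "DlcvResult", function(x)
  signatureMembers(x@signature))

#' Mean DLCV performance metrics
#'
#' @param x A \linkS4class{DlcvResult}.
#' @return Named numeric vector (percent): sensitivity, specificity, ppv,
#'   npv, accuracy, averaged over runs.
#' @export
#' @name dlcvMetrics
setMethod("dlcvMetrics", "DlcvResult", function(x) x@metrics)

#' Per-feature selection frequencies
#'
#' @param x A \linkS4class{DlcvResult}.
#' @return Named numeric vector: for every feature, the fraction of
#'   outer-training fits whose final model contained it.
#' @export
#' @name selectionFrequency
setMethod("selectionFrequency", "DlcvResult", function(x)
  x@selectionFrequency)

setMethod("show", "MirnaExpressionSet", function(object) {
  cat("MirnaExpressionSet:", nrow(object), "features x",
      ncol(object), "samples\n")
  nm <- sum(SummarizedExperiment::assay(object, "missing"))
  cat("  undetected (imputed) cells:", nm, "\n")
})

setMethod("show", "SampleAnnotation", function(object) {
  cat("SampleAnnotation:", nrow(object), "samples\n")
  print(table(object$subtype))
  extra <- setdiff(colnames(object), "subtype")
  if (length(extra)) cat("  covariates:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: ", length(object@assignments), " samples in ",
      object@k, " clusters (", object@tree$method, ")\n", sep = "")
  print(table(cluster = object@assignments))
})

setMethod("show", "SubtypeSignature", function(object) {
  cat("SubtypeSignature [", object@subtype, "]: ",
      nrow(object@members), " miRNAs\n", sep = "")
  if (nrow(object@members)) print(head(object@members, 10L))
})

setMethod("show", "DlcvResult", function(object) {
  cat("DlcvResult [", object@subtype, "]: ", object@nRuns,
      " runs, median m* = ", median(object@mStars), "\n", sep = "")
  print(round(object@metrics, 1L))
  cat("signature size:", nrow(signatureMembers(object)), "\n")
})
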