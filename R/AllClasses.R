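#' @import methods
#' @importFrom stats cor cutree hclust as.dist median p.adjust phyper
#'   rnorm runif sd wilcox.test cor.test predict setNames
#' @importFrom utils read.delim write.table head
#' @importFrom e1071 svm
#' @importFrom jsonlite write_json read_json
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames
NULL

#' Closed vocabulary of AML (cyto-)genetic subtype labels
#'
#' Canonical tokens for the six type-II aberration groups modelled by the
#' package plus the catch-all \code{"other"}. Cytogenetic notation found in
#' clinical tables (e.g. \code{"t(8;21)(q22;q22)"}, \code{"inv(16)(p13q22)"},
#' \code{"11q23"}) is mapped onto these tokens by
#' \code{\link{canonicalSubtype}}.
#'
#' @format Character vector of length 7.
#' @export
AML_SUBTYPES <- c("MLL", "t_8_21", "inv_16", "t_15_17",
                  "CEBPA_dm", "NPM1", "other")

## ---------------------------------------------------------------------------
## MirnaExpressionSet
## ---------------------------------------------------------------------------

#' Container for a log2-scale miRNA (or gene) expression matrix
#'
#' A thin extension of
#' \linkS4class{SummarizedExperiment} holding two assays:
#' \code{"log2expr"}, the features x samples expression matrix on log2 scale,
#' and \code{"missing"}, a logical mask that is \code{TRUE} where the value
#' was undetected before imputation. Feature and sample identifiers are the
#' dimnames and must be unique.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{MirnaExpressionSet}} (constructor),
#'   \code{\link{exprValues}}, \code{\link{missingMask}}
#' @export
setClass("MirnaExpressionSet", contains = "SummarizedExperiment")

setValidity("MirnaExpressionSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("log2expr", "missing") %in% a))
    return("assays 'log2expr' and 'missing' are required")
  v <- SummarizedExperiment::assay(object, "log2expr")
  m <- SummarizedExperiment::assay(object, "missing")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("feature and sample identifiers (dimnames) are required")
  if (anyDuplicated(rownames(v)))
    return(sprintf("duplicate feature identifier: %s",
                   rownames(v)[duplicated(rownames(v))][1L]))
  if (anyDuplicated(colnames(v)))
    return(sprintf("duplicate sample identifier: %s",
                   colnames(v)[duplicated(colnames(v))][1L]))
  if (!is.logical(m))
    return("'missing' assay must be logical")
  if (any(!is.finite(v[!m])))
    return("non-finite expression values outside the missing mask")
  TRUE
})

#' Construct a MirnaExpressionSet
#'
#' @param values Numeric matrix, features in rows, samples in columns, log2
#'   scale. Must carry unique rownames (miRNA ids) and colnames (sample ids).
#' @param missing Optional logical matrix of the same shape marking values
#'   that were undetected before imputation. Defaults to all-\code{FALSE}.
#' @return A \linkS4class{MirnaExpressionSet}.
#' @examples
#' v <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("miR-", 1:3), c("s1", "s2")))
#' MirnaExpressionSet(v)
#' @export
MirnaExpressionSet <- function(values, missing = NULL) {
  values <- as.matrix(values)
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  storage.mode(missing) <- "logical"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values, missing = missing))
  new("MirnaExpressionSet", se)
}

## ---------------------------------------------------------------------------
## SampleAnnotation
## ---------------------------------------------------------------------------

#' Per-sample annotation: subtype labels and optional covariates
#'
#' Extends \linkS4class{DFrame}. Row names are the unique sample
#' identifiers; the mandatory \code{subtype} column is a factor over
#' \code{\link{AML_SUBTYPES}}. Further columns are covariates, either
#' continuous (age, white blood cell count) or categorical; tri-state
#' mutation flags (present / absent / untested) are stored as factors with
#' \code{NA} meaning untested.
#'
#' @seealso \code{\link{SampleAnnotation}} (constructor),
#'   \code{\link{readSampleAnnotation}}
#' @export
setClass("SampleAnnotation", contains = "DFrame")

setValidity("SampleAnnotation", function(object) {
  if (is.null(rownames(object)))
    return("sample identifiers (row names) are required")
  if (anyDuplicated(rownames(object)))
    return(sprintf("duplicate sample identifier: %s",
                   rownames(object)[duplicated(rownames(object))][1L]))
  if (!"subtype" %in% colnames(object))
    return("a 'subtype' column is required")
  st <- object$subtype
  if (!is.factor(st) || !all(levels(st) %in% AML_SUBTYPES))
    return("'subtype' must be a factor over the closed AML subtype vocabulary")
  TRUE
})

#' Construct a SampleAnnotation
#'
#' Subtype strings are passed through \code{\link{canonicalSubtype}}, so
#' cytogenetic notation is accepted; anything outside the closed vocabulary
#' falls back to \code{"other"} with a warning.
#'
#' @param sampleIds Character vector of unique sample identifiers.
#' @param subtype Character or factor of per-sample subtype labels.
#' @param covariates Optional data.frame (or DataFrame) of additional
#'   per-sample columns, in the same order as \code{sampleIds}.
#' @return A \linkS4class{SampleAnnotation}.
#' @export
SampleAnnotation <- function(sampleIds, subtype, covariates = NULL) {
  sampleIds <- as.character(sampleIds)
  st <- factor(canonicalSubtype(as.character(subtype)), levels = AML_SUBTYPES)
  df <- S4Vectors::DataFrame(subtype = st, row.names = sampleIds)
  if (!is.null(covariates)) {
    cov <- S4Vectors::DataFrame(covariates)
    rownames(cov) <- sampleIds
    df <- cbind(df, cov)
  }
  new("SampleAnnotation", df)
}

## ---------------------------------------------------------------------------
## Configuration
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the constants used across the pipeline stages. Defaults follow
#' the study design the package emulates: a 6-fold geometric-mean expression
#' filter, 14 sample clusters, 100 double-loop cross-validation (DLCV)
#' reshuffles, a minimum subtype size of 10 for classification, and a
#' 3-of-5 database consensus rule for miRNA targets.
#'
#' @slot filterFoldThreshold positive fold-change threshold of the variance
#'   filter (linear scale; the filter works at \code{log2} of it).
#' @slot nClusters number of flat clusters cut from the sample dendrogram.
#' @slot dlcvRuns number of DLCV reshuffles (fresh outer fold partitions).
#' @slot outerFolds,innerFolds stratified fold counts of the outer
#'   (performance) and inner (signature-size selection) loops.
#' @slot featureGrid strictly increasing candidate signature sizes searched
#'   by the inner loop.
#' @slot selectionTau selection-frequency threshold in (0, 1] above which a
#'   feature enters the consolidated subtype signature.
#' @slot minGroupSize smallest subtype size accepted for classification.
#' @slot consensusMinSupport databases that must agree for a target call.
#' @slot wardMethod agglomeration convention, \code{"ward.D"} (Lance-Williams
#'   recurrence applied to the 1 - r dissimilarities as given) or
#'   \code{"ward.D2"}.
#' @slot svmCost soft-margin cost of the linear SVM (fixed, not tuned).
#' @slot rngSeed integer seed from which every stochastic stage derives its
#'   stream.
#' @seealso \code{\link{pipelineConfig}}
#' @export
setClass("PipelineConfig", representation(
  filterFoldThreshold = "numeric",
  nClusters           = "integer",
  dlcvRuns            = "integer",
  outerFolds          = "integer",
  innerFolds          = "integer",
  featureGrid         = "integer",
  selectionTau        = "numeric",
  minGroupSize        = "integer",
  consensusMinSupport = "integer",
  wardMethod          = "character",
  svmCost             = "numeric",
  rngSeed             = "integer"
))

setValidity("PipelineConfig", function(object) {
  if (object@filterFoldThreshold <= 1)
    return("filterFoldThreshold must exceed 1")
  counts <- c(object@nClusters, object@dlcvRuns, object@minGroupSize,
              object@consensusMinSupport)
  if (any(counts < 1L)) return("counts must be positive")
  if (object@outerFolds < 2L || object@innerFolds < 2L)
    return("outerFolds and innerFolds must be >= 2")
  g <- object@featureGrid
  if (length(g) == 0L || any(g < 1L) || is.unsorted(g, strictly = TRUE))
    return("featureGrid must be a strictly increasing positive sequence")
  if (object@selectionTau <= 0 || object@selectionTau > 1)
    return("selectionTau must lie in (0, 1]")
  if (!object@wardMethod %in% c("ward.D", "ward.D2"))
    return("wardMethod must be 'ward.D' or 'ward.D2'")
  if (object@svmCost <= 0) return("svmCost must be positive")
  TRUE
})

#' Create a pipeline configuration
#'
#' @param filterFoldThreshold Fold threshold of the expression filter
#'   (default 6).
#' @param nClusters Flat cluster count (default 14).
#' @param dlcvRuns DLCV reshuffles (default 100).
#' @param outerFolds,innerFolds Outer / inner stratified fold counts
#'   (defaults 3 and 5).
#' @param featureGrid Candidate signature sizes (default
#'   \code{c(1, 2, 3, 5, 8, 12, 18, 27, 40, 60)}).
#' @param selectionTau Selection-frequency threshold (default 0.5).
#' @param minGroupSize Minimum subtype size for classification (default 10).
#' @param consensusMinSupport Database agreement for target calls (default 3).
#' @param wardMethod \code{"ward.D"} (default) or \code{"ward.D2"}.
#' @param svmCost Linear SVM cost (default 1; deliberately not tuned so the
#'   inner loop searches signature size only).
#' @param rngSeed Integer master seed (default 1).
#' @return A \linkS4class{PipelineConfig}.
#' @examples
#' pipelineConfig(dlcvRuns = 25, rngSeed = 7)
#' @export
pipelineConfig <- function(filterFoldThreshold = 6,
                           nClusters = 14L,
                           dlcvRuns = 100L,
                           outerFolds = 3L,
                           innerFolds = 5L,
                           featureGrid = c(1L, 2L, 3L, 5L, 8L, 12L, 18L,
                                           27L, 40L, 60L),
                           selectionTau = 0.5,
                           minGroupSize = 10L,
                           consensusMinSupport = 3L,
                           wardMethod = "ward.D",
                           svmCost = 1,
                           rngSeed = 1L) {
  new("PipelineConfig",
      filterFoldThreshold = as.numeric(filterFoldThreshold),
      nClusters = as.integer(nClusters),
      dlcvRuns = as.integer(dlcvRuns),
      outerFolds = as.integer(outerFolds),
      innerFolds = as.integer(innerFolds),
      featureGrid = as.integer(featureGrid),
      selectionTau = as.numeric(selectionTau),
      minGroupSize = as.integer(minGroupSize),
      consensusMinSupport = as.integer(consensusMinSupport),
      wardMethod = wardMethod,
      svmCost = as.numeric(svmCost),
      rngSeed = as.integer(rngSeed))
}

## ---------------------------------------------------------------------------
## Cohort design / ground truth
## ---------------------------------------------------------------------------

#' Design of a synthetic miRNA cohort with planted subtype signatures
#'
#' Describes the cohort geometry the generator emulates: 664 assayed miRNAs
#' over 165 samples split into the six (cyto-)genetic subtype groups plus
#' "other" remainder, with per-subtype signature blocks shifted by
#' \code{effectLog2} on the log2 scale.
#'
#' @slot nFeatures number of miRNA features.
#' @slot groupSizes named integer, samples per subtype (names from
#'   \code{\link{AML_SUBTYPES}}).
#' @slot signatureSizes named integer, planted signature miRNAs per subtype.
#' @slot effectLog2 per-feature class-mean shift on log2 scale.
#' @slot directionMix fraction of up-regulated members per signature.
#' @slot baselineSd spread of per-miRNA baseline abundances (log2).
#' @slot noiseSd per-measurement noise (log2).
#' @slot missingRate fraction of cells undetected and floor-imputed.
#' @slot overlapSignatures if \code{TRUE} signatures of distinct subtypes may
#'   share miRNAs (drawn independently); default disjoint.
#' @slot rngSeed integer seed.
#' @seealso \code{\link{cohortDesign}}, \code{\link{generateCohort}}
#' @export
setClass("CohortDesign", representation(
  nFeatures         = "integer",
  groupSizes        = "integer",
  signatureSizes    = "integer",
  effectLog2        = "numeric",
  directionMix      = "numeric",
  baselineSd        = "numeric",
  noiseSd           = "numeric",
  missingRate       = "numeric",
  overlapSignatures = "logical",
  rngSeed           = "integer"
))

setValidity("CohortDesign", function(object) {
  if (object@nFeatures < 1L) return("nFeatures must be positive")
  gs <- object@groupSizes
  if (is.null(names(gs)) || !all(names(gs) %in% AML_SUBTYPES))
    return("groupSizes must be named with AML subtype tokens")
  if (any(gs < 1L)) return("group sizes must be positive")
  ss <- object@signatureSizes
  if (!all(names(ss) %in% setdiff(AML_SUBTYPES, "other")))
    return("signatureSizes must be named with non-'other' subtype tokens")
  if (any(ss < 1L)) return("signature sizes must be positive")
  if (!object@overlapSignatures && sum(ss) > object@nFeatures)
    return("disjoint signatures exceed the number of features")
  if (object@overlapSignatures && any(ss > object@nFeatures))
    return("a signature exceeds the number of features")
  if (object@effectLog2 < 0) return("effectLog2 must be non-negative")
  if (object@directionMix < 0 || object@directionMix > 1)
    return("directionMix must lie in [0, 1]")
  if (object@baselineSd < 0 || object@noiseSd < 0)
    return("standard deviations must be non-negative")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must lie in [0, 1)")
  TRUE
})

#' Create a synthetic cohort design
#'
#' Defaults reproduce the cohort structure of the pediatric AML study the
#' package emulates: 664 miRNAs, 165 samples with subtype group sizes
#' MLL 36, t(8;21) 21, inv(16) 17, t(15;17) 12, CEBPA-dm 11, NPM1 11 and 57
#' "other", planted signatures of 37/14/17/14/18/5 miRNAs respectively, and
#' a per-feature effect of log2(6) = 2.585 matching the study's 6-fold
#' expression contrast.
#'
#' @param nFeatures Number of miRNAs (default 664).
#' @param groupSizes Named integer vector of samples per subtype.
#' @param signatureSizes Named integer vector of planted signature sizes.
#' @param effectLog2 Class-mean shift per signature miRNA, log2 scale
#'   (default \code{log2(6)}).
#' @param directionMix Fraction of up-regulated members per signature
#'   (default 0.5).
#' @param baselineSd Between-miRNA baseline spread, log2 (default 3).
#' @param noiseSd Within-group measurement noise, log2 (default 1).
#' @param missingRate Undetected-cell rate (default 0; nonzero rates floor-impute
#'   undetected cells and keep them flagged in the missing mask).
#' @param overlapSignatures Allow signatures of distinct subtypes to share
#'   miRNAs (default \code{FALSE}: disjoint truth).
#' @param rngSeed Integer seed (default 1).
#' @return A \linkS4class{CohortDesign}.
#' @examples
#' d <- cohortDesign(rngSeed = 42)
#' sum(d@groupSizes)   # 165
#' @export
cohortDesign <- function(nFeatures = 664L,
                         groupSizes = c(MLL = 36L, t_8_21 = 21L,
                                        inv_16 = 17L, t_15_17 = 12L,
                                        CEBPA_dm = 11L, NPM1 = 11L,
                                        other = 57L),
                         signatureSizes = c(MLL = 37L, t_8_21 = 14L,
                                            inv_16 = 17L, t_15_17 = 14L,
                                            CEBPA_dm = 18L, NPM1 = 5L),
                         effectLog2 = log2(6),
                         directionMix = 0.5,
                         baselineSd = 3,
                         noiseSd = 1,
                         missingRate = 0,
                         overlapSignatures = FALSE,
                         rngSeed = 1L) {
  gs <- vapply(groupSizes, as.integer, integer(1L))
  ss <- vapply(signatureSizes, as.integer, integer(1L))
  new("CohortDesign",
      nFeatures = as.integer(nFeatures),
      groupSizes = gs, signatureSizes = ss,
      effectLog2 = as.numeric(effectLog2),
      directionMix = as.numeric(directionMix),
      baselineSd = as.numeric(baselineSd),
      noiseSd = as.numeric(noiseSd),
      missingRate = as.numeric(missingRate),
      overlapSignatures = isTRUE(overlapSignatures),
      rngSeed = as.integer(rngSeed))
}

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' Result of hierarchical sample clustering
#'
#' @slot tree the \code{\link[stats]{hclust}} merge history.
#' @slot assignments named integer, flat cluster index (1..k) per sample.
#' @slot correlation sample-sample Pearson correlation matrix.
#' @slot k number of flat clusters.
#' @seealso \code{\link{wardCluster}}, \code{\link{clusterEnrichment}}
#' @export
setClass("ClusterResult", representation(
  tree        = "ANY",
  assignments = "integer",
  correlation = "matrix",
  k           = "integer"
))

setValidity("ClusterResult", function(object) {
  r <- object@correlation
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8)
    return("correlation matrix must be square and symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8 || min(r) < -1 - 1e-8 || max(r) > 1 + 1e-8)
    return("correlation entries must lie in [-1, 1] with unit diagonal")
  if (length(object@assignments) != nrow(r))
    return("one assignment per sample required")
  if (!all(object@assignments %in% seq_len(object@k)))
    return("assignments must index 1..k")
  TRUE
})

#' A per-subtype miRNA signature with selection frequencies
#'
#' @slot subtype subtype token the signature discriminates.
#' @slot members data.frame with columns \code{mirna}, \code{direction}
#'   ("up"/"down", sign of the in-group minus out-group mean on the full
#'   cohort) and \code{frequency} (fraction of outer-training fits whose
#'   final model contained the miRNA), sorted by descending frequency.
#' @seealso \code{\link{dlcv}}, \code{\link{consolidateSignatures}}
#' @export
setClass("SubtypeSignature", representation(
  subtype = "character",
  members = "data.frame"
))

setValidity("SubtypeSignature", function(object) {
  m <- object@members
  need <- c("mirna", "direction", "frequency")
  if (!all(need %in% colnames(m)))
    return("members needs columns mirna, direction, frequency")
  if (nrow(m) && (any(m$frequency < 0) || any(m$frequency > 1)))
    return("frequencies must lie in [0, 1]")
  if (nrow(m) && is.unsorted(-m$frequency))
    return("members must be sorted by descending frequency")
  if (nrow(m) && !all(m$direction %in% c("up", "down")))
    return("direction must be 'up' or 'down'")
  TRUE
})

#' Report of a double-loop cross-validation run set for one subtype
#'
#' @slot subtype subtype token.
#' @slot metrics mean over runs of sensitivity, specificity, PPV, NPV and
#'   accuracy, in percent.
#' @slot runMetrics per-run metric traces (runs x 5 matrix, percent); a run's
#'   metrics come from its pooled outer-fold confusion counts, undefined
#'   ratios are \code{NaN}.
#' @slot confusionTotals confusion counts pooled over all runs (tp, fp, tn,
#'   fn).
#' @slot selectionFrequency named numeric, per-feature fraction of
#'   outer-training fits whose final model contained the feature.
#' @slot signature the consolidated \linkS4class{SubtypeSignature}.
#' @slot mStars signature size chosen by the inner loop, one per
#'   outer-training fit.
#' @slot nRuns,seed bookkeeping: run count and master seed used.
#' @seealso \code{\link{dlcv}}
#' @export
setClass("DlcvResult", representation(
  subtype            = "character",
  metrics            = "numeric",
  runMetrics         = "matrix",
  confusionTotals    = "numeric",
  selectionFrequency = "numeric",
  signature          = "ANY",
  mStars             = "integer",
  nRuns              = "integer",
  seed               = "integer"
))
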