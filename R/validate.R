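#' Canonicalize miRNA feature names for cross-platform matching
#'
#' Trims whitespace, lowercases, and strips a leading species prefix
#' ("hsa-"). Star-strand markers ("miR-126*") and arm suffixes
#' ("-3p"/"-5p") are preserved as distinct features, since passenger
#' strands are quantified separately on the arrays.
#'
#' @param ids Character vector of miRNA names.
#' @return Character vector of canonical names, same length.
#' @examples
#' canonicalizeMirnaNames(c("miR-485-5P", "hsa-miR-126*", " let-7c "))
#' @export
canonicalizeMirnaNames <- function(ids) {
  x <- tolower(trimws(as.character(ids)))
  sub("^hsa-", "", x)
}

#' Intersect a subtype signature with another platform's feature set
#'
#' Exact name matching after canonicalization
#' (\code{\link{canonicalizeMirnaNames}}); deterministic. An empty
#' intersection is a hard error: the signature cannot be tested on that
#' platform.
#'
#' @param sig A \linkS4class{SubtypeSignature}.
#' @param platformFeatures Character vector of feature ids available on the
#'   test platform.
#' @return List of class \code{PlatformIntersection} with \code{subtype},
#'   \code{requested}, \code{available}, \code{dropped} (signature names)
#'   and \code{platformIds}, the matching identifiers as spelled on the
#'   test platform.
#' @export
intersectSignature <- function(sig, platformFeatures) {
  requested <- signatureMembers(sig)$mirna
  canonReq <- canonicalizeMirnaNames(requested)
  canonPlat <- canonicalizeMirnaNames(platformFeatures)
  hit <- canonReq %in% canonPlat
  if (!any(hit))
    stop("signature for '", sig@subtype,
         "' shares no miRNAs with the platform: untestable")
  structure(list(subtype = sig@subtype,
                 requested = requested,
                 available = requested[hit],
                 dropped = requested[!hit],
                 platformIds = platformFeatures[match(canonReq[hit],
                                                      canonPlat)]),
            class = "PlatformIntersection")
}

#' Validate subtype signatures on an independent cohort
#'
#' For every signature's subtype present in both cohorts: restrict both
#' cohorts to the signature miRNAs available on the test platform,
#' standardize each cohort per feature within itself (absorbing additive
#' platform offsets), train a one-vs-rest SVM on the complete training
#' cohort, score every test sample and report
#' sensitivity/specificity/PPV/NPV/accuracy. Subtypes with fewer than
#' \code{minTestPositives} positive test samples are reported
#' \code{"insufficient"} and never silently scored; an empty feature
#' intersection reports \code{"untestable"}.
#'
#' @param trainX,trainA Training cohort
#'   (\linkS4class{MirnaExpressionSet}, \linkS4class{SampleAnnotation}).
#' @param testX,testA Independent test cohort, possibly from a different
#'   platform.
#' @param signatures List of \linkS4class{SubtypeSignature} or
#'   \linkS4class{DlcvResult}, one per subtype.
#' @param config A \linkS4class{PipelineConfig} (SVM cost).
#' @param minTestPositives Minimum positive test samples to score a subtype
#'   (default 5).
#' @param harmonize Standardize each cohort per feature within itself
#'   before training/scoring (default \code{TRUE}; turning it off exposes
#'   raw platform offsets).
#' @return List with \code{metrics}, a data.frame of per-subtype status and
#'   metrics (percent), and \code{intersections}, the per-subtype
#'   \code{PlatformIntersection}s.
#' @export
crossPlatformValidate <- function(trainX, trainA, testX, testA, signatures,
                                  config = pipelineConfig(),
                                  minTestPositives = 5L,
                                  harmonize = TRUE) {
  if (!identical(sampleIds(trainX), sampleIds(trainA)) ||
      !identical(sampleIds(testX), sampleIds(testA)))
    stop("each cohort must be aligned (alignSamples)")
  sigs <- lapply(signatures, function(s)
    if (is(s, "DlcvResult")) s@signature else s)

  standardizeRows <- function(v) {
    mu <- rowMeans(v)
    sdev <- apply(v, 1L, sd)
    sdev[sdev == 0] <- 1
    (v - mu) / sdev
  }

  rows <- list()
  inters <- list()
  for (s in sigs) {
    st <- s@subtype
    yTest <- subtypes(testA) == st
    row <- data.frame(subtype = st, status = "scored", n_test_positive =
                      sum(yTest), n_features = NA_integer_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      ppv = NA_real_, npv = NA_real_, accuracy = NA_real_,
                      stringsAsFactors = FALSE)
    if (sum(yTest) < minTestPositives) {
      row$status <- "insufficient"
      rows[[st]] <- row
      message("subtype '", st, "' has ", sum(yTest),
              " test samples; excluded from the analysis (insufficient)")
      next
    }
    pin <- tryCatch(intersectSignature(s, featureIds(testX)),
                    error = function(e) NULL)
    if (is.null(pin)) {
      row$status <- "untestable"
      rows[[st]] <- row
      next
    }
    inters[[st]] <- pin
    trainMap <- match(canonicalizeMirnaNames(pin$available),
                      canonicalizeMirnaNames(featureIds(trainX)))
    ok <- !is.na(trainMap)
    vTrain <- exprValues(trainX)[trainMap[ok], , drop = FALSE]
    vTest <- exprValues(testX)[pin$platformIds[ok], , drop = FALSE]
    rownames(vTest) <- rownames(vTrain)   # align spellings across platforms
    if (harmonize) {
      vTrain <- standardizeRows(vTrain)
      vTest <- standardizeRows(vTest)
    }
    yTrain <- subtypes(trainA) == s@subtype
    model <- trainOvrSvm(vTrain, yTrain, rownames(vTrain),
                         cost = config@svmCost)
    pred <- predict(model, vTest)
    m <- computeMetrics(tp = sum(pred & yTest), fp = sum(pred & !yTest),
                        tn = sum(!pred & !yTest), fn = sum(!pred & yTest))
    row$n_features <- nrow(vTrain)
    row[names(m)] <- m
    rows[[st]] <- row
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, intersections = inters)
}
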