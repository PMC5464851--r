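## Welch t statistics, vectorized over features. Zero pooled standard error
## with a non-zero mean gap is +Inf (a perfectly separating feature); a zero
## gap is 0 regardless of variance.
welchStatistic <- function(v, y) {
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L)
    stop("each class needs at least two samples for Welch ranking")
  x1 <- v[, y, drop = FALSE]; x0 <- v[, !y, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  se <- sqrt(v1 / n1 + v0 / n0)
  t <- abs(m1 - m0) / se
  t[se == 0 & m1 != m0] <- Inf
  t[m1 == m0] <- 0
  t
}

asValues <- function(x) {
  if (is(x, "MirnaExpressionSet")) exprValues(x) else as.matrix(x)
}

#' Rank features by two-class separation
#'
#' Orders features by decreasing absolute Welch t statistic between the two
#' classes; ties (including multiple perfectly-separating features) break by
#' lexicographic feature identifier so the ranking is deterministic.
#'
#' @param x A \linkS4class{MirnaExpressionSet} or numeric matrix
#'   (features x samples).
#' @param y Logical (or 0/1) class membership per sample; both classes need
#'   at least two samples.
#' @return Character vector of all feature identifiers, best first.
#' @export
rankFeatures <- function(x, y) {
  v <- asValues(x)
  y <- as.logical(y)
  t <- welchStatistic(v, y)
  rownames(v)[order(-t, rownames(v), method = "radix")]
}

#' Train a one-vs-rest linear SVM on selected features
#'
#' Features are standardized to zero mean and unit variance on the training
#' samples (parameters stored and re-applied at prediction), then a linear
#' soft-margin SVM with class-balanced misclassification weights
#' (\eqn{w_c = n / (2 n_c)}) is fit at fixed cost. The fit is deterministic
#' given its inputs.
#'
#' @param x Training \linkS4class{MirnaExpressionSet} or matrix.
#' @param y Logical (or 0/1) class membership per training sample.
#' @param featureSubset Non-empty character vector of feature ids to use.
#' @param cost Soft-margin cost (default 1).
#' @return An object of class \code{OvrSvmModel}; use
#'   \code{\link{predict.OvrSvmModel}} to score new samples.
#' @export
trainOvrSvm <- function(x, y, featureSubset, cost = 1) {
  if (length(featureSubset) == 0L) stop("featureSubset must be non-empty")
  v <- asValues(x)
  missing <- setdiff(featureSubset, rownames(v))
  if (length(missing))
    stop("features not in matrix: ", paste(missing, collapse = ", "))
  y <- as.logical(y)
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("each class needs at least two training samples")
  v <- v[featureSubset, , drop = FALSE]
  mu <- rowMeans(v)
  sdev <- apply(v, 1L, sd)
  sdev[sdev == 0] <- 1
  z <- t((v - mu) / sdev)
  n <- length(y)
  w <- c("TRUE" = n / (2 * sum(y)), "FALSE" = n / (2 * sum(!y)))
  fit <- e1071::svm(z, factor(y, levels = c("FALSE", "TRUE")),
                    kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = w)
  structure(list(svm = fit, mu = mu, sd = sdev, features = featureSubset),
            class = "OvrSvmModel")
}

#' Predict with a one-vs-rest SVM model
#'
#' @param object An \code{OvrSvmModel} from \code{\link{trainOvrSvm}}.
#' @param newdata A \linkS4class{MirnaExpressionSet} or matrix containing
#'   the model's features.
#' @param ... Ignored.
#' @return Named logical vector: \code{TRUE} = predicted in-class.
#' @export
predict.OvrSvmModel <- function(object, newdata, ...) {
  v <- asValues(newdata)[object$features, , drop = FALSE]
  z <- t((v - object$mu) / object$sd)
  out <- predict(object$svm, z) == "TRUE"
  names(out) <- colnames(v)
  out
}

## Stratified fold ids in 1..k, uses the current RNG stream.
stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

balancedAccuracy <- function(pred, truth) {
  (mean(pred[truth]) + mean(!pred[!truth])) / 2
}

#' Choose the signature size by inner cross-validation
#'
#' For each candidate size \eqn{m} in the grid, features are ranked on each
#' inner-training split, the top \eqn{m} are used to train a one-vs-rest
#' SVM, and mean balanced accuracy over the stratified inner folds is
#' recorded. The smallest \eqn{m} attaining the maximum mean wins (a
#' parsimony tie-break). If the minority class is too small for the
#' requested fold count, fewer folds are used with a warning; fewer than two
#' possible folds is an error.
#'
#' @param x Training \linkS4class{MirnaExpressionSet} or matrix.
#' @param y Logical class membership.
#' @param featureGrid Strictly increasing candidate sizes; entries larger
#'   than the feature count are dropped.
#' @param innerFolds Stratified fold count (default 5).
#' @param rngSeed Integer seed for the fold split.
#' @param cost SVM cost (default 1).
#' @return Integer, the chosen size m*, with the per-size mean balanced
#'   accuracies attached as attribute \code{"meanBalancedAccuracy"}.
#' @export
innerLoopSelect <- function(x, y, featureGrid, innerFolds = 5L,
                            rngSeed = 1L, cost = 1) {
  v <- asValues(x)
  y <- as.logical(y)
  grid <- featureGrid[featureGrid <= nrow(v)]
  if (length(grid) == 0L) grid <- nrow(v)
  nMin <- min(sum(y), sum(!y))
  k <- min(as.integer(innerFolds), nMin)
  if (k < 2L) stop("minority class too small to build two inner folds")
  if (k < innerFolds)
    warning("inner fold count reduced to ", k,
            " so every fold holds both classes")
  set.seed(rngSeed)
  folds <- stratifiedFolds(y, k)
  acc <- matrix(NA_real_, k, length(grid))
  for (j in seq_len(k)) {
    tr <- folds != j
    ranked <- rankFeatures(v[, tr, drop = FALSE], y[tr])
    for (mi in seq_along(grid)) {
      feats <- ranked[seq_len(grid[mi])]
      model <- trainOvrSvm(v[, tr, drop = FALSE], y[tr], feats, cost = cost)
      pred <- predict(model, v[, !tr, drop = FALSE])
      acc[j, mi] <- balancedAccuracy(pred, y[!tr])
    }
  }
  means <- colMeans(acc)
  mStar <- grid[which.max(means)]   # which.max: first (smallest) on ties
  structure(as.integer(mStar),
            meanBalancedAccuracy = setNames(means, grid))
}

#' Fit one outer-fold model: inner size selection, ranking and training
#'
#' The unit of work of the outer DLCV loop, exposed so the training-only
#' data flow can be verified directly: every step — inner fold construction,
#' size selection, feature ranking, standardization and SVM fitting — sees
#' only the columns named by \code{trainIdx}. Samples outside the training
#' index cannot influence the returned model.
#'
#' @param x Full-cohort \linkS4class{MirnaExpressionSet} or matrix.
#' @param y Logical class membership for all samples.
#' @param trainIdx Integer (or logical) index of training samples.
#' @param config A \linkS4class{PipelineConfig} (grid, inner folds, cost).
#' @param rngSeed Integer seed for the inner fold split.
#' @return List with \code{model} (\code{OvrSvmModel}), \code{features}
#'   (the final feature set) and \code{mStar}.
#' @export
fitFoldModel <- function(x, y, trainIdx, config = pipelineConfig(),
                         rngSeed = 1L) {
  v <- asValues(x)
  y <- as.logical(y)
  vtr <- v[, trainIdx, drop = FALSE]
  ytr <- y[trainIdx]
  mStar <- innerLoopSelect(vtr, ytr, config@featureGrid,
                           innerFolds = config@innerFolds,
                           rngSeed = rngSeed, cost = config@svmCost)
  feats <- rankFeatures(vtr, ytr)[seq_len(mStar)]
  model <- trainOvrSvm(vtr, ytr, feats, cost = config@svmCost)
  list(model = model, features = feats, mStar = as.integer(mStar))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy in percent. A ratio with zero denominator is returned as
#' \code{NaN} (flagged undefined), never silently zero.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; must not all be zero.
#' @return Named numeric vector (percent): \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}, \code{accuracy}.
#' @examples
#' computeMetrics(tp = 9, fp = 5, tn = 85, fn = 1)
#' @export
computeMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NaN else 100 * num / den
  c(sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv         = ratio(tp, tp + fp),
    npv         = ratio(tn, tn + fn),
    accuracy    = 100 * (tp + tn) / total)
}

#' Double-loop cross-validated signature discovery for one subtype
#'
#' One-vs-rest classification of \code{subtype} against all other samples.
#' Each of \code{dlcvRuns} runs draws a fresh stratified partition into
#' \code{outerFolds} outer folds; on every outer-training set the inner
#' loop (\code{\link{innerLoopSelect}}) picks the signature size m*,
#' features are re-ranked on the full outer-training set, the top-m* model
#' is trained and scored on the held-out fold, and the run's confusion
#' counts are pooled into sensitivity/specificity/PPV/NPV/accuracy. The
#' report averages per-run metrics. A feature's selection frequency is the
#' fraction of outer-training fits whose final model contained it; the
#' consolidated signature keeps features at frequency >= tau, capped at the
#' median m* over fits, with directions taken from the sign of the in-group
#' minus out-group mean on the full cohort.
#'
#' @param x A \linkS4class{MirnaExpressionSet} (typically after
#'   \code{\link{filterVariableMirnas}}, or the full matrix).
#' @param a A \linkS4class{SampleAnnotation} aligned to \code{x}.
#' @param subtype Subtype token; its group must hold at least
#'   \code{config@minGroupSize} samples.
#' @param config A \linkS4class{PipelineConfig}; \code{rngSeed} drives all
#'   resampling.
#' @return A \linkS4class{DlcvResult}.
#' @seealso \code{\link{dlcvAllSubtypes}}, \code{\link{computeMetrics}},
#'   \code{\link{consolidateSignatures}}
#' @export
dlcv <- function(x, a, subtype, config = pipelineConfig()) {
  if (!identical(sampleIds(x), sampleIds(a)))
    stop("expression and annotation must be aligned (alignSamples)")
  y <- subtypes(a) == subtype
  nPos <- sum(y)
  if (nPos < config@minGroupSize)
    stop("subtype '", subtype, "' has ", nPos,
         " samples, below the minimum group size of ", config@minGroupSize)
  v <- exprValues(x)
  seedBase <- config@rngSeed %% 100000000L
  runs <- config@dlcvRuns
  kOut <- config@outerFolds

  selCount <- setNames(numeric(nrow(v)), rownames(v))
  mStars <- integer(0L)
  runMetrics <- matrix(NA_real_, runs, 5L,
                       dimnames = list(NULL, c("sensitivity", "specificity",
                                               "ppv", "npv", "accuracy")))
  totals <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (r in seq_len(runs)) {
    set.seed(seedBase + r)
    outer <- stratifiedFolds(y, kOut)
    conf <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (k in seq_len(kOut)) {
      trainIdx <- which(outer != k)
      fit <- fitFoldModel(v, y, trainIdx, config,
                          rngSeed = seedBase + 1000L * r + k)
      selCount[fit$features] <- selCount[fit$features] + 1
      mStars <- c(mStars, fit$mStar)
      testIdx <- which(outer == k)
      pred <- predict(fit$model, v[, testIdx, drop = FALSE])
      truth <- y[testIdx]
      conf <- conf + c(tp = sum(pred & truth), fp = sum(pred & !truth),
                       tn = sum(!pred & !truth), fn = sum(!pred & truth))
    }
    runMetrics[r, ] <- computeMetrics(conf[["tp"]], conf[["fp"]],
                                      conf[["tn"]], conf[["fn"]])
    totals <- totals + conf
  }

  freq <- selCount / (runs * kOut)
  inMean <- rowMeans(v[, y, drop = FALSE])
  outMean <- rowMeans(v[, !y, drop = FALSE])
  direction <- ifelse(inMean >= outMean, "up", "down")

  cand <- names(freq)[freq >= config@selectionTau]
  cand <- cand[order(-freq[cand], cand, method = "radix")]
  cap <- as.integer(ceiling(median(mStars)))
  cand <- head(cand, cap)
  members <- data.frame(mirna = cand,
                        direction = direction[cand],
                        frequency = unname(freq[cand]),
                        stringsAsFactors = FALSE)
  signature <- new("SubtypeSignature", subtype = subtype, members = members)

  new("DlcvResult",
      subtype = subtype,
      metrics = colMeans(runMetrics, na.rm = TRUE),
      runMetrics = runMetrics,
      confusionTotals = totals,
      selectionFrequency = freq,
      signature = signature,
      mStars = mStars,
      nRuns = runs,
      seed = config@rngSeed)
}

#' Run DLCV signature discovery for every eligible subtype
#'
#' Applies \code{\link{dlcv}} to each non-"other" subtype with at least
#' \code{config@minGroupSize} samples; smaller groups are skipped with a
#' message.
#'
#' @inheritParams dlcv
#' @param subtypeSet Subtype tokens to consider (default: all non-"other").
#' @return Named list of \linkS4class{DlcvResult}.
#' @export
dlcvAllSubtypes <- function(x, a, config = pipelineConfig(),
                            subtypeSet = setdiff(AML_SUBTYPES, "other")) {
  counts <- table(factor(subtypes(a), levels = AML_SUBTYPES))
  eligible <- subtypeSet[counts[subtypeSet] >= config@minGroupSize]
  skipped <- setdiff(subtypeSet[counts[subtypeSet] > 0L], eligible)
  if (length(skipped))
    message("skipping subtype(s) below the minimum group size: ",
            paste(skipped, collapse = ", "))
  out <- lapply(eligible, function(st) dlcv(x, a, st, config))
  names(out) <- eligible
  out
}

#' Consolidate per-subtype signatures into a union set
#'
#' De-duplicates the union of signature members across subtypes. Each miRNA
#' keeps one row per subtype it serves (with that subtype's direction and
#' frequency); the union size counts distinct miRNAs — the study-level
#' "47 miRNAs" style summary.
#'
#' @param signatures Non-empty list of \linkS4class{SubtypeSignature} or
#'   \linkS4class{DlcvResult}.
#' @return List with \code{members} (data.frame subtype/mirna/direction/
#'   frequency), \code{unionMirnas} (character) and \code{unionSize}.
#' @export
consolidateSignatures <- function(signatures) {
  if (length(signatures) == 0L) stop("at least one signature is required")
  sigs <- lapply(signatures, function(s)
    if (is(s, "DlcvResult")) s@signature else s)
  rows <- do.call(rbind, lapply(sigs, function(s) {
    m <- signatureMembers(s)
    if (nrow(m) == 0L) return(NULL)
    data.frame(subtype = s@subtype, m, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(subtype = character(), mirna = character(),
                       direction = character(), frequency = numeric())
  unionMirnas <- sort(unique(rows$mirna))
  list(members = rows, unionMirnas = unionMirnas,
       unionSize = length(unionMirnas))
}
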