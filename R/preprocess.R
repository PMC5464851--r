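#' Normalize raw Ct values to log2 expression
#'
#' Applies the standard TaqMan-array median-centering convention: for each
#' sample the expression of feature \eqn{f} is
#' \eqn{\mathrm{median}_{f'}(Ct_{f's}) - Ct_{fs}}, so one unit equals one
#' doubling and higher values mean higher abundance. Undetected cells (the
#' missing mask) enter the calculation as \code{undetectedCt} — the
#' detection-limit convention for Ct arrays — and stay flagged in the
#' output mask. The per-sample median of the output is exactly zero.
#'
#' @param ct A \linkS4class{MirnaExpressionSet} holding raw Ct values
#'   (missing cells may be \code{NA} under the mask).
#' @param undetectedCt Ct value imputed for undetected cells (default 40,
#'   the usual cycle ceiling).
#' @return A \linkS4class{MirnaExpressionSet} of log2-scale expression.
#' @examples
#' ct <- MirnaExpressionSet(matrix(c(20, 25, 30), 3, 1,
#'   dimnames = list(paste0("miR-", 1:3), "s1")))
#' exprValues(normalizeCt(ct))   # 5, 0, -5
#' @export
normalizeCt <- function(ct, undetectedCt = 40) {
  v <- exprValues(ct)
  m <- missingMask(ct)
  v[m] <- undetectedCt
  allMissing <- colSums(!m) == 0L
  if (any(allMissing))
    stop("sample(s) with all Ct values missing: ",
         paste(colnames(v)[allMissing], collapse = ", "))
  med <- apply(v, 2L, median)
  expr <- sweep(-v, 2L, -med)
  MirnaExpressionSet(expr, m)
}

#' Filter miRNAs by fold change against the cohort geometric mean
#'
#' Retains a miRNA when at least one sample deviates from the cohort
#' geometric mean by the fold threshold or more, i.e. on the log2 scale
#' \deqn{\max_s |x_{fs} - \overline{x}_{f\cdot}| \ge \log_2(\mathrm{fold})}
#' where the per-feature mean of log2 values equals the log2 geometric mean
#' of the linear abundances. The comparison is inclusive; feature order is
#' preserved. The filter is invariant to adding a global constant on the
#' log2 scale (i.e. to rescaling all linear abundances by one factor).
#'
#' @param x A \linkS4class{MirnaExpressionSet}, log2 scale.
#' @param foldThreshold Fold-change threshold, must exceed 1 (default 6,
#'   the study's "6-fold higher or lower" rule).
#' @return List with \code{expression} (the retained features) and
#'   \code{report}, a list with \code{nInputFeatures}, \code{nRetained},
#'   \code{retainedIds} and \code{thresholdLog2}.
#' @export
filterVariableMirnas <- function(x, foldThreshold = 6) {
  if (foldThreshold <= 1)
    stop("foldThreshold must exceed 1 (the filter would be vacuous)")
  v <- exprValues(x)
  thr <- log2(foldThreshold)
  dev <- abs(v - rowMeans(v))
  keep <- apply(dev, 1L, max) >= thr
  report <- list(nInputFeatures = nrow(v),
                 nRetained = sum(keep),
                 retainedIds = rownames(v)[keep],
                 thresholdLog2 = thr)
  list(expression = x[keep, ], report = report)
}
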