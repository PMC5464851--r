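#' Generate a synthetic miRNA cohort with planted subtype signatures
#'
#' Draws a features x samples log2 expression matrix according to the
#' additive model
#' \deqn{x_{fs} = b_f + \delta \, e \, 1[f \in S(g_s)] + \epsilon_{fs}}
#' with per-miRNA baselines \eqn{b_f \sim N(0, \sigma_b^2)}, measurement
#' noise \eqn{\epsilon \sim N(0, \sigma_n^2)}, and a signed effect
#' \eqn{\delta e} (\eqn{\delta = \pm 1} per the signature's direction) added
#' to the planted signature miRNAs \eqn{S(g)} of the sample's subtype
#' \eqn{g}. Cells are marked undetected uniformly at the design's missing
#' rate and imputed at the cohort floor (the minimum simulated value),
#' emulating detection-limit behavior of Ct-based arrays. Identical designs
#' (including seed) give identical cohorts.
#'
#' @param design A \linkS4class{CohortDesign}.
#' @return List with elements \code{expression}
#'   (\linkS4class{MirnaExpressionSet}), \code{annotation}
#'   (\linkS4class{SampleAnnotation}) and \code{truth} (list with
#'   \code{plantedSignatures}, a per-subtype data.frame of \code{mirna} and
#'   \code{direction}, and \code{sampleLabels}).
#' @examples
#' coh <- generateCohort(cohortDesign(nFeatures = 50,
#'   groupSizes = c(MLL = 10L, other = 10L),
#'   signatureSizes = c(MLL = 5L), rngSeed = 1))
#' dim(exprValues(coh$expression))
#' @export
generateCohort <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  nf <- design@nFeatures
  gs <- design@groupSizes
  ns <- sum(gs)
  set.seed(design@rngSeed)

  featIds <- sprintf("miR-sim-%04d", seq_len(nf))
  sampIds <- sprintf("AML-%03d", seq_len(ns))
  labels <- rep(names(gs), gs)

  baseline <- rnorm(nf, 0, design@baselineSd)
  values <- baseline + matrix(rnorm(nf * ns, 0, design@noiseSd), nf, ns)
  dimnames(values) <- list(featIds, sampIds)

  ss <- design@signatureSizes
  planted <- list()
  if (design@overlapSignatures) {
    pick <- lapply(ss, function(k) sample.int(nf, k))
  } else {
    pool <- sample.int(nf, sum(ss))
    ends <- cumsum(ss)
    pick <- lapply(seq_along(ss), function(i)
      pool[(c(0L, ends)[i] + 1L):ends[i]])
    names(pick) <- names(ss)
  }
  for (g in names(ss)) {
    f <- pick[[g]]
    nUp <- round(design@directionMix * length(f))
    dir <- rep(c("up", "down"), c(nUp, length(f) - nUp))
    dir <- dir[sample.int(length(dir))]
    delta <- ifelse(dir == "up", 1, -1) * design@effectLog2
    inGroup <- labels == g
    values[f, inGroup] <- values[f, inGroup] + delta
    planted[[g]] <- data.frame(mirna = featIds[f], direction = dir,
                               stringsAsFactors = FALSE)
  }

  miss <- matrix(runif(nf * ns) < design@missingRate, nf, ns,
                 dimnames = dimnames(values))
  if (any(miss)) values[miss] <- min(values[!miss])

  list(expression = MirnaExpressionSet(values, miss),
       annotation = SampleAnnotation(sampIds, labels),
       truth = list(plantedSignatures = planted, sampleLabels = labels))
}

#' Generate a paired mRNA matrix whose genes track their miRNAs
#'
#' For each selected miRNA \eqn{m}, \code{nTargetsPerMirna} synthetic target
#' genes are drawn as \eqn{g = c \cdot m + N(0, \sigma^2)} with coupling
#' \eqn{c \le 0}, emulating the inverse correlation expected between a miRNA
#' and the transcripts it represses.
#'
#' @param truth Truth component of \code{\link{generateCohort}} output; its
#'   planted signature miRNAs are the regulators simulated.
#' @param mirna The miRNA \linkS4class{MirnaExpressionSet} of the cohort.
#' @param coupling Linear coupling coefficient in [-1, 0] (default -1).
#' @param nTargetsPerMirna Genes per miRNA (default 3).
#' @param noiseSd Residual gene noise (default 1; 0 gives exact linear maps).
#' @param rngSeed Integer seed (default 1).
#' @return List with \code{expression} (gene-level
#'   \linkS4class{MirnaExpressionSet}) and \code{targetMap}, a data.frame of
#'   true (\code{mirna}, \code{gene}) pairs.
#' @export
generatePairedMrna <- function(truth, mirna, coupling = -1,
                               nTargetsPerMirna = 3L, noiseSd = 1,
                               rngSeed = 1L) {
  if (coupling > 0) stop("coupling must be <= 0")
  mirs <- unique(unlist(lapply(truth$plantedSignatures, `[[`, "mirna")))
  mirs <- intersect(mirs, featureIds(mirna))
  if (length(mirs) == 0L) stop("no planted miRNAs present in the matrix")
  set.seed(rngSeed)
  v <- exprValues(mirna)
  rows <- vector("list", length(mirs) * nTargetsPerMirna)
  genes <- character(length(rows))
  map <- data.frame(mirna = rep(mirs, each = nTargetsPerMirna),
                    gene = NA_character_, stringsAsFactors = FALSE)
  i <- 0L
  for (m in mirs) {
    for (k in seq_len(nTargetsPerMirna)) {
      i <- i + 1L
      genes[i] <- sprintf("GENE-%s-%02d", sub("^miR-", "", m), k)
      rows[[i]] <- coupling * v[m, ] + rnorm(ncol(v), 0, noiseSd)
    }
  }
  map$gene <- genes
  g <- do.call(rbind, rows)
  dimnames(g) <- list(genes, colnames(v))
  list(expression = MirnaExpressionSet(g), targetMap = map)
}

#' Emulate a second measurement platform
#'
#' Restricts the matrix to a uniform random subset of features
#' (\code{floor(keepFraction * n)} of them, at least one) and adds a
#' per-feature additive offset drawn from \eqn{N(0, shiftSd^2)}, emulating
#' the partial probe overlap and batch offsets of an independent array
#' platform.
#'
#' @param x A \linkS4class{MirnaExpressionSet}.
#' @param keepFraction Fraction of features retained, in (0, 1].
#' @param shiftSd Standard deviation of the per-feature offsets (>= 0).
#' @param rngSeed Integer seed (default 1).
#' @return A \linkS4class{MirnaExpressionSet} on the reduced feature set,
#'   features in their original order.
#' @export
generateSecondPlatform <- function(x, keepFraction = 0.6, shiftSd = 2,
                                   rngSeed = 1L) {
  if (keepFraction <= 0 || keepFraction > 1)
    stop("keepFraction must lie in (0, 1]")
  if (shiftSd < 0) stop("shiftSd must be non-negative")
  nf <- nrow(x)
  nKeep <- max(1L, as.integer(floor(keepFraction * nf)))
  set.seed(rngSeed)
  keep <- sort(sample.int(nf, nKeep))
  v <- exprValues(x)[keep, , drop = FALSE]
  m <- missingMask(x)[keep, , drop = FALSE]
  v <- v + rnorm(nKeep, 0, shiftSd)
  MirnaExpressionSet(v, m)
}
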