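#' Pearson correlation distance between sample profiles
#'
#' \eqn{d(i, j) = 1 - r(i, j)} with \eqn{r} the Pearson correlation of the
#' two samples' expression profiles across features, giving values in
#' [0, 2]. The distance is invariant to per-sample affine rescaling of the
#' profiles. Samples with zero profile variance have no defined correlation
#' and are a hard error.
#'
#' @param x A \linkS4class{MirnaExpressionSet} with at least two features.
#' @return A \code{\link[stats]{dist}} object over samples, with the
#'   correlation matrix attached as attribute \code{"correlation"}.
#' @export
pearsonDistance <- function(x) {
  v <- exprValues(x)
  if (nrow(v) < 2L) stop("at least two features are required")
  sds <- apply(v, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance sample profile: ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  r <- cor(v)
  d <- as.dist(1 - r)
  attr(d, "correlation") <- r
  d
}

#' Ward hierarchical clustering of a sample distance matrix
#'
#' Agglomerates samples under the Ward minimum-variance criterion via the
#' Lance-Williams recurrence. With \code{method = "ward.D"} (the default)
#' the recurrence is applied to the dissimilarities as given — the
#' convention this pipeline pairs with the 1 - r correlation distance;
#' \code{"ward.D2"} squares them first. Cutting the tree at \code{k} yields
#' the flat assignments.
#'
#' @param d A \code{\link[stats]{dist}} from \code{\link{pearsonDistance}}
#'   (any dist works; the correlation attribute is used when present).
#' @param k Number of flat clusters, 1 <= k <= n.
#' @param method \code{"ward.D"} (default) or \code{"ward.D2"}.
#' @return A \linkS4class{ClusterResult}.
#' @export
wardCluster <- function(d, k, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  n <- attr(d, "Size")
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie between 1 and the sample count")
  tree <- hclust(d, method = method)
  assignments <- cutree(tree, k = k)
  r <- attr(d, "correlation")
  if (is.null(r)) {
    r <- 1 - as.matrix(d)
    diag(r) <- 1
  }
  new("ClusterResult", tree = tree, assignments = assignments,
      correlation = r, k = k)
}

#' Test clusters for subtype and covariate enrichment
#'
#' For every (cluster, categorical level) pair, the one-sided hypergeometric
#' tail probability of drawing at least the observed number of labelled
#' samples in a cluster of that size (over-representation test). Continuous
#' covariates (e.g. age, white blood cell count) are compared in-cluster vs
#' out-of-cluster with a two-sided Wilcoxon rank-sum test. P-values are
#' Benjamini-Hochberg adjusted within each label family (the subtype column
#' and each covariate separately). Covariates that are entirely missing are
#' skipped with a warning; \code{NA} entries (e.g. untested mutation flags)
#' are excluded pairwise.
#'
#' @param clusters A \linkS4class{ClusterResult}.
#' @param a A \linkS4class{SampleAnnotation} aligned to the clustered
#'   samples (same identifiers).
#' @param covariates Character vector of covariate columns to test
#'   (default: all columns besides \code{subtype}).
#' @return data.frame with columns \code{cluster}, \code{family},
#'   \code{label}, \code{count_in_cluster}, \code{cluster_size},
#'   \code{count_total}, \code{p_value}, \code{adjusted_p}.
#' @export
clusterEnrichment <- function(clusters, a,
                              covariates = setdiff(colnames(a), "subtype")) {
  cl <- clusterAssignments(clusters)
  if (!setequal(names(cl), sampleIds(a)) ||
      length(cl) != nrow(a))
    stop("annotation samples must match the clustered samples; ",
         "run alignSamples() first")
  a <- a[names(cl), , drop = FALSE]
  n <- length(cl)
  rows <- list()

  testCategorical <- function(values, family) {
    values <- as.factor(values)
    for (kk in sort(unique(cl))) {
      inCl <- cl == kk
      for (lev in levels(values)) {
        labelled <- !is.na(values) & values == lev
        K <- sum(labelled)
        q <- sum(labelled & inCl)
        m <- sum(inCl)
        ## P(X >= q), X ~ Hypergeom(total n, K labelled, draw m)
        p <- phyper(q - 1L, K, n - K, m, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <<- data.frame(
          cluster = kk, family = family, label = lev,
          count_in_cluster = q, cluster_size = m, count_total = K,
          p_value = p, stringsAsFactors = FALSE)
      }
    }
  }

  testCategorical(subtypes(a), "subtype")
  for (cv in covariates) {
    values <- a[[cv]]
    if (all(is.na(values))) {
      warning("covariate '", cv, "' is entirely missing; skipped")
      next
    }
    if (is.numeric(values)) {
      for (kk in sort(unique(cl))) {
        inside <- values[cl == kk]
        outside <- values[cl != kk]
        if (sum(!is.na(inside)) == 0L || sum(!is.na(outside)) == 0L) next
        p <- suppressWarnings(
          wilcox.test(inside, outside, exact = FALSE)$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = kk, family = cv, label = cv,
          count_in_cluster = NA_integer_, cluster_size = sum(cl == kk),
          count_total = sum(!is.na(values)), p_value = p,
          stringsAsFactors = FALSE)
      }
    } else {
      testCategorical(values, cv)
    }
  }

  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  for (fam in unique(out$family)) {
    idx <- out$family == fam
    out$adjusted_p[idx] <- p.adjust(out$p_value[idx], method = "BH")
  }
  rownames(out) <- NULL
  out
}
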