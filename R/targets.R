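#' Load miRNA-target prediction databases
#'
#' Each database is a two-column TSV (\code{mirna_id}, \code{gene_id}), one
#' file per database; pairs are de-duplicated within a database. The
#' package never bundles or downloads real prediction databases
#' (microcosm/miRecords/miRTarBase/PITA/TargetScan releases are versioned
#' external resources); tests run on synthetic fixtures.
#'
#' @param paths Named character vector: \code{name = path}. Names become
#'   the database names.
#' @return List of class \code{TargetDatabaseSet}: \code{databases}, a
#'   named list of data.frames with columns \code{mirna_id} and
#'   \code{gene_id}, and \code{nDatabases}.
#' @export
readTargetDatabases <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("'paths' must be a named vector (name = path)")
  if (anyDuplicated(names(paths)))
    stop("database names must be unique")
  dbs <- lapply(paths, function(p) {
    df <- read.delim(p, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("mirna_id", "gene_id") %in% colnames(df)))
      stop("database file ", p, " needs columns mirna_id and gene_id")
    unique(df[, c("mirna_id", "gene_id")])
  })
  structure(list(databases = dbs, nDatabases = length(dbs)),
            class = "TargetDatabaseSet")
}

#' Build a TargetDatabaseSet from in-memory pair tables
#'
#' @param databases Named list of data.frames with columns \code{mirna_id}
#'   and \code{gene_id}.
#' @return A \code{TargetDatabaseSet}.
#' @export
targetDatabaseSet <- function(databases) {
  if (is.null(names(databases))) stop("databases must be named")
  dbs <- lapply(databases, function(df)
    unique(df[, c("mirna_id", "gene_id")]))
  structure(list(databases = dbs, nDatabases = length(dbs)),
            class = "TargetDatabaseSet")
}

#' Consensus miRNA-target calls across prediction databases
#'
#' Every distinct (miRNA, gene) pair appearing in any database receives one
#' call; its support is the number of databases reporting it, and the pair
#' is called a target when support reaches \code{minSupport} — the
#' "reported in at least three of five databases" rule. Output is sorted by
#' miRNA, then descending support, then gene. The target set is monotone
#' decreasing in \code{minSupport}.
#'
#' @param dbs A \code{TargetDatabaseSet}.
#' @param minSupport Required database agreement, between 1 and the number
#'   of databases (default 3).
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{support}, \code{is_target}.
#' @export
consensusTargets <- function(dbs, minSupport = 3L) {
  if (minSupport < 1L || minSupport > dbs$nDatabases)
    stop("minSupport must lie between 1 and the number of databases (",
         dbs$nDatabases, ")")
  all <- do.call(rbind, lapply(dbs$databases, function(df)
    data.frame(key = paste(df$mirna_id, df$gene_id, sep = "\r"),
               mirna_id = df$mirna_id, gene_id = df$gene_id,
               stringsAsFactors = FALSE)))
  support <- table(all$key)
  first <- all[!duplicated(all$key), ]
  out <- data.frame(mirna_id = first$mirna_id,
                    gene_id = first$gene_id,
                    support = as.integer(support[first$key]),
                    stringsAsFactors = FALSE)
  out$is_target <- out$support >= minSupport
  out <- out[order(out$mirna_id, -out$support, out$gene_id,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Screen consensus targets for inverse miRNA-mRNA correlation
#'
#' Repressed targets should anti-correlate with their miRNA. For every
#' called target pair present in both matrices, the Spearman rank
#' correlation across the shared samples is computed (rank-based, hence
#' invariant under monotone transforms of either profile; Pearson available
#' by flag); a pair is \code{consistent} when the correlation is negative.
#' P-values are Benjamini-Hochberg adjusted across all tested pairs. Pairs
#' whose miRNA or gene is absent from the matrices are listed untested.
#'
#' @param mirnaX miRNA \linkS4class{MirnaExpressionSet}.
#' @param mrnaX gene-level \linkS4class{MirnaExpressionSet} sharing samples
#'   with \code{mirnaX} (aligned via \code{\link{alignSamples}} logic).
#' @param calls data.frame from \code{\link{consensusTargets}}; only rows
#'   with \code{is_target} are screened.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{correlation}, \code{p_value}, \code{adjusted_p},
#'   \code{consistent}, \code{tested}.
#' @export
inverseCorrelation <- function(mirnaX, mrnaX, calls,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(sampleIds(mirnaX), sampleIds(mrnaX))
  if (length(shared) < 4L)
    stop("fewer than 4 shared samples; correlation is meaningless")
  vm <- exprValues(mirnaX)[, shared, drop = FALSE]
  vg <- exprValues(mrnaX)[, shared, drop = FALSE]
  targets <- calls[calls$is_target, , drop = FALSE]
  out <- data.frame(mirna_id = targets$mirna_id,
                    gene_id = targets$gene_id,
                    correlation = NA_real_, p_value = NA_real_,
                    adjusted_p = NA_real_, consistent = NA,
                    tested = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    m <- out$mirna_id[i]; g <- out$gene_id[i]
    if (!(m %in% rownames(vm)) || !(g %in% rownames(vg))) next
    ct <- suppressWarnings(cor.test(vm[m, ], vg[g, ], method = method,
                                    exact = FALSE))
    out$correlation[i] <- unname(ct$estimate)
    out$p_value[i] <- ct$p.value
    out$consistent[i] <- out$correlation[i] < 0
    out$tested[i] <- TRUE
  }
  out$adjusted_p[out$tested] <- p.adjust(out$p_value[out$tested],
                                         method = "BH")
  out
}
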