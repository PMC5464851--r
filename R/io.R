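#' Map subtype labels onto the closed vocabulary
#'
#' Clinical tables mix cytogenetic notations; this maps common spellings
#' (e.g. \code{"t(8;21)(q22;q22)"}, \code{"inv(16)"}, \code{"11q23"},
#' \code{"CEBPA.dm"}) onto the canonical tokens of
#' \code{\link{AML_SUBTYPES}}. Labels that match nothing become
#' \code{"other"}, with one warning listing them.
#'
#' @param labels Character vector of subtype labels.
#' @return Character vector of canonical tokens, same length.
#' @examples
#' canonicalSubtype(c("t(8;21)(q22;q22)", "MLL-rearranged", "NPM1"))
#' @export
canonicalSubtype <- function(labels) {
  raw <- as.character(labels)
  x <- tolower(gsub("[[:space:]]", "", raw))
  out <- rep(NA_character_, length(x))
  out[x %in% tolower(AML_SUBTYPES)] <-
    AML_SUBTYPES[match(x[x %in% tolower(AML_SUBTYPES)],
                       tolower(AML_SUBTYPES))]
  pat <- list(
    MLL      = "^(t\\(9;11\\).*|t\\(10;11\\).*|t\\(11;19\\).*|11q23.*|mll.*|kmt2a.*)$",
    t_8_21   = "^t\\(8;21\\).*",
    inv_16   = "^(inv\\(16\\).*|cbfb-?myh11)$",
    t_15_17  = "^(t\\(15;17\\).*|pml-?rara?)$",
    CEBPA_dm = "^cebpa.*",
    NPM1     = "^npm1.*"
  )
  for (tok in names(pat)) {
    hit <- is.na(out) & grepl(pat[[tok]], x)
    out[hit] <- tok
  }
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown subtype label(s) mapped to 'other': ",
            paste(unique(raw[unknown]), collapse = ", "))
    out[unknown] <- "other"
  }
  out
}

#' Read a tab-separated expression matrix
#'
#' Expects one header row and one leading identifier column; remaining cells
#' are numeric or the missing token. Missing cells are recorded in the
#' missing mask and carried as \code{NA} until imputation (see
#' \code{\link{normalizeCt}} and \code{\link{generateCohort}} for the
#' floor-imputation convention).
#'
#' @param path File path of a TSV file.
#' @param orientation \code{"features_in_rows"} (default, typical array
#'   export) or \code{"samples_in_rows"}; the returned object is always
#'   features x samples.
#' @param missingToken String marking undetected cells (default "NA").
#' @return A \linkS4class{MirnaExpressionSet}.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("features_in_rows",
                                                 "samples_in_rows"),
                                 missingToken = "NA") {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L]))
    stop("ragged row at line ", which(widths != widths[1L])[1L] ,
         " (expected ", widths[1L], " fields, found ",
         widths[widths != widths[1L]][1L], ")")
  header <- fields[[1L]][-1L]
  ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate identifier in rows: ", ids[duplicated(ids)][1L])
  if (anyDuplicated(header))
    stop("duplicate identifier in header: ", header[duplicated(header)][1L])
  cells <- t(vapply(fields[-1L], function(f) f[-1L],
                    character(length(header))))
  if (length(header) == 1L) cells <- matrix(cells, ncol = 1L)
  miss <- cells == missingToken
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (any(is.na(vals) & !miss))
    stop("non-numeric cell that is not the missing token '",
         missingToken, "'")
  dimnames(vals) <- list(ids, header)
  dimnames(miss) <- dimnames(vals)
  if (orientation == "samples_in_rows") {
    vals <- t(vals)
    miss <- t(miss)
  }
  vals[miss] <- NA_real_
  x <- MirnaExpressionSet(vals, miss)
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}: features in rows, one
#' identifier column, masked cells written as the missing token. Values are
#' written with full precision (\code{format(..., digits = 17)}) so a
#' write-read round trip is exact.
#'
#' @param x A \linkS4class{MirnaExpressionSet}.
#' @param path Output file path.
#' @param missingToken Token for masked cells (default "NA").
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path, missingToken = "NA") {
  v <- exprValues(x)
  m <- missingMask(x)
  cells <- matrix(vapply(as.vector(v), function(z)
    format(z, digits = 17L, scientific = TRUE), character(1L)),
    nrow(v), ncol(v))
  cells[m] <- missingToken
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(v)), collapse = "\t"), con)
  writeLines(paste(rownames(v),
                   apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"),
             con)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated with columns \code{sample_id}, \code{subtype}, then any
#' covariates. Subtype spellings are canonicalized via
#' \code{\link{canonicalSubtype}}.
#'
#' @param path File path of a TSV file.
#' @return A \linkS4class{SampleAnnotation}.
#' @export
readSampleAnnotation <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("annotation file must have a 'sample_id' column")
  if (!"subtype" %in% colnames(df))
    stop("annotation file must have a 'subtype' column")
  cov <- df[, setdiff(colnames(df), c("sample_id", "subtype")),
            drop = FALSE]
  SampleAnnotation(df$sample_id, df$subtype,
                   covariates = if (ncol(cov)) cov else NULL)
}

#' Write a sample annotation table as TSV
#'
#' @param a A \linkS4class{SampleAnnotation}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSampleAnnotation <- function(a, path) {
  df <- as.data.frame(a)
  out <- data.frame(sample_id = rownames(df), df, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix and an annotation to their shared samples
#'
#' Both objects are subset to the intersection of their sample identifiers,
#' in the order the samples appear in the expression matrix. Dropped sample
#' counts are reported via \code{message()}; an empty intersection is an
#' error. The operation is idempotent.
#'
#' @param x A \linkS4class{MirnaExpressionSet}.
#' @param a A \linkS4class{SampleAnnotation}.
#' @return List with elements \code{expression} and \code{annotation}.
#' @export
alignSamples <- function(x, a) {
  shared <- intersect(sampleIds(x), sampleIds(a))
  if (length(shared) == 0L)
    stop("no shared samples between expression matrix and annotation")
  dropX <- ncol(x) - length(shared)
  dropA <- nrow(a) - length(shared)
  if (dropX || dropA)
    message("alignSamples: dropped ", dropX, " expression and ", dropA,
            " annotation samples outside the intersection")
  keep <- sampleIds(x)[sampleIds(x) %in% shared]
  list(expression = x[, keep],
       annotation = new("SampleAnnotation", a[keep, , drop = FALSE]))
}

#' Write subtype signatures as JSON
#'
#' Serializes a list of \linkS4class{SubtypeSignature} objects as
#' \code{{subtype: [{mirna, direction, frequency}, ...], ...}}.
#'
#' @param signatures List of \linkS4class{SubtypeSignature}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSignaturesJson <- function(signatures, path) {
  payload <- lapply(signatures, signatureMembers)
  names(payload) <- vapply(signatures, function(s) s@subtype, character(1L))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Read subtype signatures from JSON
#'
#' @param path Path of a file written by \code{\link{writeSignaturesJson}}.
#' @return Named list of \linkS4class{SubtypeSignature}.
#' @export
readSignaturesJson <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(payload), function(st) {
    m <- as.data.frame(payload[[st]])
    m <- m[order(-m$frequency, m$mirna), , drop = FALSE]
    rownames(m) <- NULL
    new("SubtypeSignature", subtype = st, members = m)
  })
  names(out) <- names(payload)
  out
}
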