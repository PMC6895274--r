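#' Read a query-anchored protein alignment
#'
#' Reads an aligned FASTA, A2M, or Stockholm file and anchors it to a query
#' sequence: alignment columns where the query carries a gap are dropped, so
#' the stored columns correspond one-to-one with query residues 1..L. For A2M
#' input, insert-state columns (lowercase residues or \code{"."}) are treated
#' as gap-equivalent and removed with their columns.
#'
#' @param path path to the alignment file.
#' @param format \code{"auto"} (by extension: \code{.sto}/\code{.stk}/
#'   \code{.stockholm} for Stockholm, \code{.a2m} for A2M, FASTA otherwise)
#'   or one of \code{"fasta"}, \code{"a2m"}, \code{"stockholm"}.
#' @param query id of the query record; defaults to the first record.
#' @return a [QueryAlignment-class] object.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">q", "AKD-E", ">h1", "AKDCE", ">h2", "SKECE"), f)
#' aln <- readAlignment(f)
#' queryLength(aln)  # 4: the query-gap column was dropped
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "a2m", "stockholm"),
                          query = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
                     sto = , stk = , stockholm = "stockholm",
                     a2m = "a2m",
                     "fasta")
  }
  if (format == "stockholm") {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(msa)
    ids <- names(seqs)
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    seqs <- as.character(ss)
    ids <- names(ss)
  }
  if (length(seqs) == 0L) stop("empty alignment: ", path)
  if (length(seqs) < 2L) stop("fewer than 2 sequences in alignment")
  ids <- sub("\\s.*$", "", ids)  # keep the id token only
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: rows differ in length")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids

  if (format == "a2m") {
    # A2M insert columns: any lowercase or '.' entry marks the column as an
    # insert state; inserts are gap-equivalent and dropped wholesale.
    insert <- apply(m, 2L, function(col)
      any(col == "." | (col %in% letters)))
    m <- m[, !insert, drop = FALSE]
    if (ncol(m) == 0L) stop("alignment has no match columns")
  }
  m[m == "."] <- GAP_CHAR
  m[] <- toupper(m)

  bad <- setdiff(unique(as.vector(m)), c(AA_STANDARD, GAP_CHAR))
  if (length(bad))
    stop("non-standard residue character(s) in alignment: ",
         paste(bad, collapse = " "))

  if (is.null(query)) query <- ids[1L]
  hits <- which(rownames(m) == query)
  if (length(hits) == 0L) stop("query id not found: ", query)
  if (length(hits) > 1L) stop("query id is not unique: ", query)

  keep <- which(m[hits, ] != GAP_CHAR)
  if (length(keep) == 0L) stop("query sequence is all gaps")
  new("QueryAlignment",
      seqMat = m[, keep, drop = FALSE],
      queryId = query,
      sourceColumns = as.integer(keep))
}

#' Write a query-anchored alignment as aligned FASTA
#'
#' @param aln a [QueryAlignment-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "QueryAlignment"))
  seqs <- apply(aln@seqMat, 1L, paste0, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln@seqMat)
  Biostrings::writeXStringSet(ss, filepath = path, format = "fasta")
  invisible(path)
}

#' @describeIn readAlignment number of query residues L.
#' @param x a \code{QueryAlignment}.
#' @export
queryLength <- function(x) {
  stopifnot(is(x, "QueryAlignment"))
  ncol(x@seqMat)
}

#' @describeIn readAlignment id of the query row.
#' @export
queryId <- function(x) {
  stopifnot(is(x, "QueryAlignment"))
  x@queryId
}

#' @describeIn readAlignment the ungapped query sequence as a character
#'   vector of one-letter residues.
#' @export
querySeq <- function(x) {
  stopifnot(is(x, "QueryAlignment"))
  x@seqMat[match(x@queryId, rownames(x@seqMat)), ]
}

#' @describeIn readAlignment number of aligned sequences.
#' @export
nSeq <- function(x) {
  stopifnot(is(x, "QueryAlignment"))
  nrow(x@seqMat)
}

#' @describeIn readAlignment map from query position to original input-file
#'   column (1-based).
#' @export
posMap <- function(x) {
  stopifnot(is(x, "QueryAlignment"))
  stats::setNames(x@sourceColumns, seq_along(x@sourceColumns))
}

#' @describeIn readAlignment the alignment as a character matrix
#'   (rows = sequences, columns = query positions).
#' @export
alnMatrix <- function(x) {
  stopifnot(is(x, "QueryAlignment"))
  x@seqMat
}

setMethod("show", "QueryAlignment", function(object) {
  cat(sprintf("QueryAlignment: %d sequences x %d query positions (query '%s')\n",
              nrow(object@seqMat), ncol(object@seqMat), object@queryId))
  q <- paste0(querySeq(object), collapse = "")
  if (nchar(q) > 60) q <- paste0(substr(q, 1, 57), "...")
  cat("  query: ", q, "\n", sep = "")
})
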