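#' Flag gap-heavy and invariant alignment columns
#'
#' Columns whose gap fraction strictly exceeds \code{maxGapFrac} are flagged
#' \code{masked_gap}; columns whose non-gap residues are all identical are
#' flagged \code{masked_invariant} (gap masking takes precedence). Only
#' \code{retained} columns enter the covariation analysis.
#'
#' @param aln a [QueryAlignment-class].
#' @param maxGapFrac gap-fraction cutoff in [0, 1); default 0.2, i.e. columns
#'   with more than 20\% gaps are masked.
#' @return a [ColumnMask-class].
#' @export
applyColumnFilters <- function(aln, maxGapFrac = 0.2) {
  stopifnot(is(aln, "QueryAlignment"))
  if (!is.numeric(maxGapFrac) || length(maxGapFrac) != 1L ||
      maxGapFrac < 0 || maxGapFrac >= 1)
    stop("maxGapFrac must lie in [0, 1)")
  m <- aln@seqMat
  gapFrac <- colMeans(m == GAP_CHAR)
  invariant <- apply(m, 2L, function(col) {
    r <- col[col != GAP_CHAR]
    length(unique(r)) == 1L
  })
  status <- ifelse(gapFrac > maxGapFrac, "masked_gap",
                   ifelse(invariant, "masked_invariant", "retained"))
  new("ColumnMask",
      position = seq_len(ncol(m)),
      column = aln@sourceColumns,
      gapFraction = unname(gapFrac),
      status = unname(status),
      maxGapFrac = maxGapFrac)
}

#' @describeIn applyColumnFilters query positions whose columns survived both
#'   filters.
#' @param mask a \code{ColumnMask}.
#' @export
retainedPositions <- function(mask) {
  stopifnot(is(mask, "ColumnMask"))
  mask@position[mask@status == "retained"]
}

#' @describeIn applyColumnFilters the mask as a data.frame (position, column,
#'   gapFraction, status), suitable for a TSV report.
#' @export
maskReport <- function(mask) {
  stopifnot(is(mask, "ColumnMask"))
  data.frame(position = mask@position,
             column = mask@column,
             gapFraction = mask@gapFraction,
             status = mask@status)
}

setMethod("show", "ColumnMask", function(object) {
  tab <- table(factor(object@status,
                      levels = c("retained", "masked_gap", "masked_invariant")))
  cat(sprintf(
    "ColumnMask: %d positions (%d retained, %d gap-masked at >%g, %d invariant)\n",
    length(object@position), tab[["retained"]], tab[["masked_gap"]],
    object@maxGapFrac, tab[["masked_invariant"]]))
})

#' Filter unaligned homologs against a query sequence
#'
#' Retains candidate sequences whose global-alignment identity to the query is
#' strictly below \code{maxIdentity} and whose length is within
#' \code{[lenLo, lenHi]} times the query length. Identity is computed as the
#' number of matching aligned residues divided by the length of the shorter
#' sequence, under a BLOSUM62 Needleman-Wunsch alignment. When fewer than
#' \code{minN} sequences survive, the set is flagged insufficient (a warning
#' is raised and the \code{sufficient} attribute is \code{FALSE}): such a
#' protein should be excluded from coupling analysis.
#'
#' @param seqs named character vector of candidate homolog sequences
#'   (ungapped, one-letter amino acids).
#' @param query the query sequence (ungapped string).
#' @param maxIdentity retain only identity < this fraction (default 0.90).
#' @param lenLo,lenHi allowed length ratio to the query (default 0.7-1.3,
#'   inclusive).
#' @param minN minimum survivor count considered sufficient (default 10).
#' @return the surviving subset of \code{seqs}, with attributes
#'   \code{sufficient} (logical) and \code{identity} (per-survivor identity).
#' @export
filterHomologs <- function(seqs, query, maxIdentity = 0.90,
                           lenLo = 0.7, lenHi = 1.3, minN = 10) {
  if (length(seqs) == 0L) stop("empty homolog set")
  if (!nzchar(query)) stop("query sequence is empty")
  qlen <- nchar(query)
  ratio <- nchar(seqs) / qlen
  lenOk <- ratio >= lenLo & ratio <= lenHi
  ident <- rep(NA_real_, length(seqs))
  if (any(lenOk)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(seqs[lenOk]),
      subject = Biostrings::AAString(query),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    shorter <- pmin(nchar(seqs[lenOk]), qlen)
    ident[lenOk] <- Biostrings::nmatch(pa) / shorter
  }
  keep <- lenOk & ident < maxIdentity
  out <- seqs[keep]
  sufficient <- length(out) >= minN
  if (!sufficient)
    warning(sprintf(
      "insufficient homologs: %d survive filtering (< %d); exclude protein",
      length(out), minN), call. = FALSE)
  attr(out, "sufficient") <- sufficient
  attr(out, "identity") <- unname(ident[keep])
  out
}
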