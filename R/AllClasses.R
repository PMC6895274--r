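#' @import methods
NULL

# The 20 standard amino acids, alphabetical one-letter order.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Query-anchored protein multiple sequence alignment
#'
#' Holds an MSA as a character matrix over the 20 standard amino acids plus
#' the gap character \code{"-"}, with one designated query row. Columns where
#' the query carries a gap are dropped at construction, so stored column
#' \code{p} corresponds exactly to query residue \code{p}; the protein length
#' \code{L} equals the number of stored columns. \code{sourceColumns} records,
#' for provenance, which 1-based column of the original input file each query
#' position came from.
#'
#' @slot seqMat character matrix, one row per sequence, one column per query
#'   position; entries are uppercase amino-acid letters or \code{"-"}.
#' @slot queryId id of the query row (must match exactly one row name).
#' @slot sourceColumns integer vector, length \code{ncol(seqMat)}, strictly
#'   increasing; original input-file column per query position.
#' @export
setClass("QueryAlignment",
  representation(seqMat = "matrix",
                 queryId = "character",
                 sourceColumns = "integer"))

setValidity("QueryAlignment", function(object) {
  m <- object@seqMat
  msgs <- character()
  if (!is.character(m) || nrow(m) < 2L)
    msgs <- c(msgs, "alignment needs at least 2 sequences")
  if (is.null(rownames(m)))
    msgs <- c(msgs, "sequence rows must be named")
  if (sum(rownames(m) == object@queryId) != 1L)
    msgs <- c(msgs, sprintf("query id '%s' must occur exactly once",
                            object@queryId))
  bad <- setdiff(unique(as.vector(m)), c(AA_STANDARD, GAP_CHAR))
  if (length(bad))
    msgs <- c(msgs, paste0("non-standard residue character(s): ",
                           paste(bad, collapse = " ")))
  if (ncol(m) < 1L)
    msgs <- c(msgs, "query has no residues (L must be >= 1)")
  if (length(object@sourceColumns) != ncol(m) ||
      is.unsorted(object@sourceColumns, strictly = TRUE))
    msgs <- c(msgs, "sourceColumns must be strictly increasing, one per column")
  qr <- match(object@queryId, rownames(m))
  if (length(msgs) == 0L && anyNA(qr) == FALSE &&
      any(m[qr, ] == GAP_CHAR))
    msgs <- c(msgs, "query row may not contain gaps after anchoring")
  if (length(msgs)) msgs else TRUE
})

#' Column retention mask for a query-anchored alignment
#'
#' Per query position: gap fraction over all rows and a status flag.
#' \code{masked_gap} marks columns whose gap fraction strictly exceeds
#' \code{maxGapFrac}; \code{masked_invariant} marks columns whose non-gap
#' residues are all identical (and that are not already gap-masked); all other
#' columns are \code{retained} and enter the covariation analysis.
#'
#' @slot position integer query positions (1..L).
#' @slot column integer source-file columns (provenance).
#' @slot gapFraction numeric in [0, 1].
#' @slot status character, one of retained / masked_gap / masked_invariant.
#' @slot maxGapFrac the gap-fraction cutoff used.
#' @export
setClass("ColumnMask",
  representation(position = "integer",
                 column = "integer",
                 gapFraction = "numeric",
                 status = "character",
                 maxGapFrac = "numeric"))

setValidity("ColumnMask", function(object) {
  n <- length(object@position)
  if (length(object@gapFraction) != n || length(object@status) != n ||
      length(object@column) != n)
    return("position, column, gapFraction and status must have equal length")
  if (any(object@gapFraction < 0 | object@gapFraction > 1))
    return("gapFraction must lie in [0, 1]")
  if (!all(object@status %in% c("retained", "masked_gap", "masked_invariant")))
    return("unknown status value")
  TRUE
})

#' McBASC covariation matrix over query positions
#'
#' Symmetric L-by-L matrix of substitution-pattern correlations. Entries for
#' pairs touching a masked column are \code{NA}; degenerate retained pairs
#' (zero variance, or fewer usable sequence pairs than \code{minSeqPairs})
#' are 0 by convention. The diagonal is \code{NA} (self-pairs are excluded).
#'
#' @slot scores numeric L x L matrix of Pearson correlations in [-1, 1].
#' @slot retained logical vector: which positions entered the analysis.
#' @slot minSeqPairs minimum usable sequence-pair count per column pair.
#' @export
setClass("CovariationMatrix",
  representation(scores = "matrix",
                 retained = "logical",
                 minSeqPairs = "integer"))

setValidity("CovariationMatrix", function(object) {
  s <- object@scores
  if (nrow(s) != ncol(s)) return("scores must be square")
  if (length(object@retained) != nrow(s))
    return("retained flag needed for every position")
  v <- s[!is.na(s)]
  if (length(v) && (max(v) > 1 + 1e-8 || min(v) < -1 - 1e-8))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' Selected evolutionary couplings (top 2L pairs)
#'
#' The budget = round(multiplier x L) highest-covariation eligible column
#' pairs, plus the per-residue partner lists C_i derived from them.
#'
#' @slot pairs data.frame with columns i, j (i < j) and score, ordered by
#'   decreasing score (ties: i, then j ascending).
#' @slot partners list of length L; element i is the integer vector of coupled
#'   partner positions of residue i.
#' @slot budget integer selection budget.
#' @slot L query protein length.
#' @slot multiplier the length multiplier that produced the budget.
#' @export
setClass("CouplingSet",
  representation(pairs = "data.frame",
                 partners = "list",
                 budget = "integer",
                 L = "integer",
                 multiplier = "numeric"))

setValidity("CouplingSet", function(object) {
  p <- object@pairs
  if (!all(c("i", "j", "score") %in% names(p)))
    return("pairs needs columns i, j, score")
  if (nrow(p) && any(p$i >= p$j)) return("pairs must satisfy i < j")
  if (length(object@partners) != object@L)
    return("partners list must have one entry per residue")
  if (sum(lengths(object@partners)) != 2L * nrow(p))
    return("sum of |C_i| must equal 2 x number of selected pairs")
  TRUE
})

#' Amino-acid pair counts for one coupled column pair
#'
#' Counts n(alpha, beta) of residue pairs observed in alignment rows with
#' non-gap residues at both columns; N is the number of contributing rows.
#'
#' @slot counts 20 x 20 integer matrix, rows = residue at column i, columns =
#'   residue at column j.
#' @slot N total contributing rows, equal to \code{sum(counts)}.
#' @slot i,j the query positions of the pair.
#' @export
setClass("PairCountTable",
  representation(counts = "matrix", N = "integer",
                 i = "integer", j = "integer"))

setValidity("PairCountTable", function(object) {
  if (!identical(dim(object@counts), c(20L, 20L)))
    return("counts must be 20 x 20")
  if (sum(object@counts) != object@N)
    return("N must equal the total count")
  TRUE
})
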