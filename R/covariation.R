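# Build the sequence-pair similarity matrix for a set of alignment columns:
# one row per unordered sequence pair (k < l), one column per requested
# position. Entry = McLachlan similarity of the two residues in that column;
# NA when either residue is a gap.
.pairSimilarity <- function(seqMat, positions) {
  n <- nrow(seqMat)
  kl <- which(upper.tri(diag(n)), arr.ind = TRUE)  # k < l
  k <- kl[, 1L]; l <- kl[, 2L]
  X <- matrix(NA_real_, nrow = length(k), ncol = length(positions))
  for (ci in seq_along(positions)) {
    a <- seqMat[, positions[ci]]
    ak <- a[k]; al <- a[l]
    ok <- ak != GAP_CHAR & al != GAP_CHAR
    if (any(ok))
      X[ok, ci] <- .MCLACHLAN[cbind(ak[ok], al[ok])]
  }
  X
}

#' McBASC covariation of two alignment columns
#'
#' The McLachlan-based substitution correlation of query positions \code{i}
#' and \code{j}: for each column, the vector of McLachlan similarities over
#' all unordered sequence pairs (k < l) with non-gap residues at both columns
#' in both sequences is formed, and the Pearson correlation of the two vectors
#' is returned. Degenerate cases (either vector constant, or fewer than
#' \code{minSeqPairs} usable sequence pairs) score 0 by convention.
#'
#' @param aln a [QueryAlignment-class].
#' @param i,j distinct query positions; both must be retained in \code{mask}.
#' @param mask a [ColumnMask-class] from [applyColumnFilters()].
#' @param minSeqPairs minimum usable sequence-pair count (default 10).
#' @return a correlation in [-1, 1].
#' @export
columnPairCovariation <- function(aln, i, j, mask, minSeqPairs = 10) {
  stopifnot(is(aln, "QueryAlignment"), is(mask, "ColumnMask"))
  if (i == j) stop("i and j must differ")
  ret <- retainedPositions(mask)
  if (!(i %in% ret) || !(j %in% ret))
    stop("covariation requested for a masked column")
  X <- .pairSimilarity(aln@seqMat, c(i, j))
  ok <- stats::complete.cases(X)
  if (sum(ok) < 2L) stop("fewer than 2 usable sequence pairs")
  .safeCor(X[ok, 1L], X[ok, 2L], minSeqPairs)
}

.safeCor <- function(x, y, minSeqPairs) {
  if (length(x) < minSeqPairs) return(0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Full McBASC covariation matrix
#'
#' Computes [columnPairCovariation()] for every unordered pair of retained
#' query positions. Pairs touching a masked column are \code{NA}; the
#' diagonal is \code{NA}. The result depends only on the set of sequences,
#' not their order.
#'
#' @inheritParams columnPairCovariation
#' @return a [CovariationMatrix-class].
#' @export
covariationMatrix <- function(aln, mask, minSeqPairs = 10) {
  stopifnot(is(aln, "QueryAlignment"), is(mask, "ColumnMask"))
  L <- queryLength(aln)
  ret <- retainedPositions(mask)
  if (length(ret) < 2L) stop("fewer than 2 retained columns")
  X <- .pairSimilarity(aln@seqMat, ret)
  hasNA <- anyNA(X)
  if (hasNA) {
    counts <- crossprod(!is.na(X))
    suppressWarnings(C <- stats::cor(X, use = "pairwise.complete.obs"))
    C[counts < minSeqPairs] <- 0
  } else {
    if (nrow(X) < minSeqPairs) {
      C <- matrix(0, length(ret), length(ret))
    } else {
      sds <- apply(X, 2L, stats::sd)
      suppressWarnings(C <- stats::cor(X))
      C[sds == 0, ] <- 0
      C[, sds == 0] <- 0
    }
  }
  C[is.na(C)] <- 0  # zero-variance convention
  C <- pmin(pmax(C, -1), 1)
  scores <- matrix(NA_real_, L, L)
  scores[ret, ret] <- C
  diag(scores) <- NA_real_
  retained <- seq_len(L) %in% ret
  new("CovariationMatrix", scores = scores, retained = retained,
      minSeqPairs = as.integer(minSeqPairs))
}

#' @describeIn covariationMatrix the covariation scores as a plain L x L
#'   matrix (NA for masked pairs and the diagonal).
#' @param cov a \code{CovariationMatrix}.
#' @export
covScores <- function(cov) {
  stopifnot(is(cov, "CovariationMatrix"))
  cov@scores
}

setMethod("show", "CovariationMatrix", function(object) {
  L <- nrow(object@scores)
  nret <- sum(object@retained)
  cat(sprintf("CovariationMatrix: %d positions (%d retained, %d pairs scored)\n",
              L, nret, nret * (nret - 1) / 2))
})
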