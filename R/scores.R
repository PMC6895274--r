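#' Percentile-normalized coupling number (CN) per residue
#'
#' Counts the selected couplings of each residue and converts the counts to
#' percentile ranks on [0, 1]: \code{CN = (rank - 1) / (L - 1)} with ranks
#' ascending in the count and averaged over ties. A CN of 1 marks the most
#' coupled residue of the protein, 0 the least coupled; all L residues
#' (including masked, zero-coupling ones) participate in the ranking.
#'
#' @param cs a [CouplingSet-class].
#' @param L protein length (defaults to the coupling set's L).
#' @return data.frame with columns \code{position}, \code{couplingCount},
#'   \code{CN}.
#' @export
couplingNumber <- function(cs, L = NULL) {
  stopifnot(is(cs, "CouplingSet"))
  if (is.null(L)) L <- cs@L
  counts <- couplingCounts(cs)
  stopifnot(length(counts) == L)
  data.frame(position = seq_len(L),
             couplingCount = as.integer(counts),
             CN = percentileRank(counts))
}

#' @describeIn couplingNumber the percentile-rank normalization itself:
#'   \code{(rank - 1) / (n - 1)} with average ranks for ties, mapping a count
#'   vector onto [0, 1].
#' @param counts numeric vector of per-residue counts (length >= 2).
#' @export
percentileRank <- function(counts) {
  if (length(counts) < 2L) stop("percentile normalization needs L >= 2")
  (rank(counts, ties.method = "average") - 1) / (length(counts) - 1)
}

#' Amino-acid pair counts for a coupled column pair
#'
#' Tallies the residue pairs (column \code{i}, column \code{j}) over all
#' alignment rows with non-gap residues at both columns. The query row always
#' contributes, so the wild-type pair count is at least 1.
#'
#' @param aln a [QueryAlignment-class].
#' @param i,j query positions.
#' @param cs optional [CouplingSet-class]; when given, (i, j) must be a
#'   selected coupling.
#' @return a [PairCountTable-class].
#' @export
pairCounts <- function(aln, i, j, cs = NULL) {
  stopifnot(is(aln, "QueryAlignment"))
  if (!is.null(cs)) {
    p <- couplingPairs(cs)
    if (!any((p$i == min(i, j)) & (p$j == max(i, j))))
      stop(sprintf("(%d, %d) is not a selected coupling", i, j))
  }
  a <- aln@seqMat[, i]
  b <- aln@seqMat[, j]
  ok <- a != GAP_CHAR & b != GAP_CHAR
  tab <- table(factor(a[ok], levels = AA_STANDARD),
               factor(b[ok], levels = AA_STANDARD))
  counts <- matrix(as.integer(tab), 20L, 20L,
                   dimnames = list(AA_STANDARD, AA_STANDARD))
  new("PairCountTable", counts = counts, N = as.integer(sum(ok)),
      i = as.integer(i), j = as.integer(j))
}

#' @describeIn pairCounts the 20 x 20 count matrix.
#' @param t a \code{PairCountTable}.
#' @export
pairCountMatrix <- function(t) {
  stopifnot(is(t, "PairCountTable"))
  t@counts
}

setMethod("show", "PairCountTable", function(object) {
  cat(sprintf("PairCountTable for pair (%d, %d): N = %d rows, %d distinct pairs\n",
              object@i, object@j, object@N, sum(object@counts > 0)))
})

#' Entropy difference of a substitution at a coupled pair
#'
#' For a substitution alpha -> gamma at column i, with beta the wild-type
#' (query) residue at the coupled partner column j, the change in the
#' log-multinomial entropy of the pair distribution is
#' \deqn{\Delta S_{i,j}(\alpha \to \gamma) =
#'   -\ln\frac{n_{i,j}(\gamma,\beta) + 1}{n_{i,j}(\alpha,\beta)}.}
#' Positive values mean the variant pair is rarer among homologs than the
#' wild-type pair (evolutionarily unfavorable).
#'
#' @param t a [PairCountTable-class].
#' @param alpha wild-type residue at column i; \code{n(alpha, beta)} must be
#'   at least 1 (the query row guarantees this when alpha matches the query).
#' @param beta wild-type residue at the partner column j.
#' @param gamma alternate residue at column i.
#' @return the entropy difference (natural log).
#' @export
deltaEntropy <- function(t, alpha, beta, gamma) {
  stopifnot(is(t, "PairCountTable"))
  aa <- c(alpha, beta, gamma)
  if (!all(aa %in% AA_STANDARD))
    stop("non-standard residue letter(s): ",
         paste(setdiff(aa, AA_STANDARD), collapse = " "))
  nab <- t@counts[alpha, beta]
  if (nab == 0L)
    stop(sprintf("n(%s, %s) = 0: wild type inconsistent with the alignment",
                 alpha, beta))
  -log((t@counts[gamma, beta] + 1) / nab)
}

#' Cost of coupling (CC) of a variant
#'
#' Averages [deltaEntropy()] over all coupled partners j of the variant
#' position i, taking beta as the query residue at each partner column:
#' \deqn{CC_i(\alpha \to \gamma) = \frac{\sum_{j \in C_i}
#'   \Delta S_{i,j}(\alpha \to \gamma)}{|C_i|}.}
#' Residues with no coupled partners get CC = 0.
#'
#' @param aln a [QueryAlignment-class].
#' @param cs a [CouplingSet-class].
#' @param v a variant: token (\code{"K329E"}), list, or 1-row data.frame with
#'   position / wt / alt. The wild type must match the query residue.
#' @return the CC value.
#' @export
costOfCoupling <- function(aln, cs, v) {
  stopifnot(is(aln, "QueryAlignment"), is(cs, "CouplingSet"))
  v <- .asVariant(v)
  q <- querySeq(aln)
  if (v$position < 1L || v$position > length(q))
    stop("variant position outside the query protein")
  if (q[v$position] != v$wt)
    stop(sprintf("wild type mismatch at %d: query has %s, variant says %s",
                 v$position, q[v$position], v$wt))
  C <- couplingPartners(cs, v$position)
  if (length(C) == 0L) return(0)
  dS <- vapply(C, function(j) {
    t <- pairCounts(aln, v$position, j)
    deltaEntropy(t, alpha = v$wt, beta = q[j], gamma = v$alt)
  }, numeric(1L))
  mean(dS)
}

#' Coevolution (CE) score
#'
#' The product of the percentile-normalized coupling number and the cost of
#' coupling: \code{CE = CN x CC}.
#'
#' @param cn CN value in [0, 1].
#' @param cc CC value.
#' @return \code{cn * cc}.
#' @export
ceScore <- function(cn, cc) {
  stopifnot(all(cn >= 0 & cn <= 1, na.rm = TRUE))
  cn * cc
}

#' Single-column conservation (CS) score
#'
#' The single-column analog of [deltaEntropy()]: with \code{n(alpha)} and
#' \code{n(gamma)} the non-gap residue counts of the variant column,
#' \code{CS = -ln((n(gamma) + 1) / n(alpha))}. High values mean the alternate
#' residue is rare in the column, i.e. the site is conserved against it.
#'
#' @inheritParams costOfCoupling
#' @return the CS value.
#' @export
csScore <- function(aln, v) {
  stopifnot(is(aln, "QueryAlignment"))
  v <- .asVariant(v)
  q <- querySeq(aln)
  if (v$position < 1L || v$position > length(q))
    stop("variant position outside the query protein")
  if (q[v$position] != v$wt)
    stop(sprintf("wild type mismatch at %d: query has %s, variant says %s",
                 v$position, q[v$position], v$wt))
  col <- aln@seqMat[, v$position]
  col <- col[col != GAP_CHAR]
  nAlpha <- sum(col == v$wt)
  nGamma <- sum(col == v$alt)
  -log((nGamma + 1) / nAlpha)
}

#' Score a batch of variants on one alignment
#'
#' Runs the full pipeline once per alignment (column filters, McBASC
#' covariation, top-2L coupling selection, CN profile) and scores every
#' variant: CN of its residue, CC over its coupled partners, CE = CN x CC,
#' and optionally CS. Per-variant problems (wild-type mismatch, position out
#' of range) are reported in the \code{flags} column without aborting the
#' batch; variants at masked columns or at residues without partners are
#' flagged and get CC = 0, hence CE = 0.
#'
#' @param aln a [QueryAlignment-class].
#' @param variants data.frame from [parseVariants()] or a character vector of
#'   tokens.
#' @param multiplier coupling-budget multiplier (default 2, the 2L rule).
#' @param maxGapFrac column gap filter (default 0.2).
#' @param minSeqPairs McBASC minimum sequence-pair count (default 10).
#' @param withCS also compute the CS conservation score (default TRUE).
#' @return data.frame with one row per variant: \code{token}, \code{position},
#'   \code{wt}, \code{alt}, \code{couplingCount}, \code{nPartners}, \code{CN},
#'   \code{CC}, \code{CE}, \code{CS} (if requested), \code{flags}.
#' @export
scoreVariants <- function(aln, variants, multiplier = 2, maxGapFrac = 0.2,
                          minSeqPairs = 10, withCS = TRUE) {
  stopifnot(is(aln, "QueryAlignment"))
  if (is.character(variants)) variants <- parseVariants(variants)
  stopifnot(is.data.frame(variants), nrow(variants) >= 1L)
  mask <- applyColumnFilters(aln, maxGapFrac = maxGapFrac)
  cov <- covariationMatrix(aln, mask, minSeqPairs = minSeqPairs)
  cs <- selectCouplings(cov, L = queryLength(aln), multiplier = multiplier)
  prof <- couplingNumber(cs)
  q <- querySeq(aln)
  L <- queryLength(aln)

  n <- nrow(variants)
  out <- data.frame(token = variants$token,
                    position = variants$position,
                    wt = variants$wt, alt = variants$alt,
                    couplingCount = NA_integer_, nPartners = NA_integer_,
                    CN = NA_real_, CC = NA_real_, CE = NA_real_,
                    flags = "")
  if (withCS) out$CS <- NA_real_
  for (r in seq_len(n)) {
    pos <- variants$position[r]
    flags <- character(0)
    if (pos < 1L || pos > L) {
      out$flags[r] <- "bad_position"
      next
    }
    if (q[pos] != variants$wt[r]) {
      out$flags[r] <- "wt_mismatch"
      next
    }
    v <- list(position = pos, wt = variants$wt[r], alt = variants$alt[r])
    out$couplingCount[r] <- prof$couplingCount[pos]
    out$nPartners[r] <- length(couplingPartners(cs, pos))
    out$CN[r] <- prof$CN[pos]
    out$CC[r] <- costOfCoupling(aln, cs, v)
    out$CE[r] <- ceScore(out$CN[r], out$CC[r])
    if (withCS) out$CS[r] <- csScore(aln, v)
    if (mask@status[pos] != "retained") flags <- c(flags, "masked_site")
    if (out$nPartners[r] == 0L) flags <- c(flags, "no_partners")
    out$flags[r] <- paste(flags, collapse = ";")
  }
  out
}
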